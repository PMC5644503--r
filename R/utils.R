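`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage RNG seed from a master seed
#'
#' Each pipeline stage draws from its own RNG stream so stages can be re-run
#' individually and reproducibly. The stage seed is a deterministic hash of the
#' master seed and the stage name, kept below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stage character stage name, e.g. `"founders"`.
#' @return An integer seed.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 1000003
  as.integer((abs(master) %% 2147483 * 997 + h * 104729 + 12345) %% 2147483629)
}

stop_poly <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_cols <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_poly("%s is missing required column(s): %s", what,
              paste(miss, collapse = ", "))
  }
}

# format doubles so that write->read round-trips to the identical binary value
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

zscale <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop_poly("cannot standardize: zero variance")
  (x - mean(x)) / s
}
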