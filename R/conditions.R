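#' @keywords internal
"_PACKAGE"

# Classed conditions. Every error raised by the package carries
# class c("imprintvc_<code>", "imprintvc_error") so callers can branch on the
# code without string-matching messages.

abort_imp <- function(code, msg, ..., data = NULL) {
  cond <- errorCondition(
    msg,
    data = data,
    ...,
    class = c(paste0("imprintvc_", tolower(code)), "imprintvc_error")
  )
  stop(cond)
}

warn_imp <- function(code, msg, ...) {
  cond <- warningCondition(
    msg,
    ...,
    class = c(paste0("imprintvc_", tolower(code)), "imprintvc_warning")
  )
  warning(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
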