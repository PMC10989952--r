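# Structured one-line logs on stderr; silenced via option(heatcompose.quiet).
hc_log <- function(msg) {
  if (!isTRUE(getOption("heatcompose.quiet", FALSE))) {
    message(sprintf("[heatcompose] %s", msg))
  }
  invisible(msg)
}
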