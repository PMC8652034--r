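# Classed conditions so callers (and the CLI) can map failures to exit codes.
.err <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "sse2dError", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

ioError          <- function(fmt, ...) .err("ioError", fmt, ...)
emptyStructureError <- function(fmt, ...) .err("emptyStructureError", fmt, ...)
emptyDomainError <- function(fmt, ...) .err("emptyDomainError", fmt, ...)
geometryError    <- function(fmt, ...) .err("geometryError", fmt, ...)
usageError       <- function(fmt, ...) .err("usageError", fmt, ...)
generationError  <- function(fmt, ...) .err("generationError", fmt, ...)
unsupportedTopologyError <- function(fmt, ...) .err("unsupportedTopologyError", fmt, ...)
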