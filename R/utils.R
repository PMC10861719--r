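# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.assert <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) .stopf(fmt, ...)
  invisible(TRUE)
}

.is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

.is_prop <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Boolean state encoding used by the GRN and perturbation modules.
.STATES <- c("UP", "DOWN", "UNCHANGED")

.state_to_num <- function(s) {
  out <- integer(length(s))
  out[s == "UP"] <- 1L
  out[s == "DOWN"] <- -1L
  bad <- !s %in% .STATES
  if (any(bad)) .stopf("invalid Boolean state(s): %s",
                       paste(unique(s[bad]), collapse = ", "))
  out
}

.num_to_state <- function(x) {
  ifelse(x > 0, "UP", ifelse(x < 0, "DOWN", "UNCHANGED"))
}

# Look up states for arbitrary genes; genes absent from the map are
# UNCHANGED (optionally with a warning naming them).
.states_for <- function(states, genes, warn = FALSE) {
  out <- unname(states[genes])
  miss <- is.na(out)
  if (any(miss)) {
    if (warn) .warnf("gene(s) absent from state map treated as UNCHANGED: %s",
                     paste(unique(genes[miss]), collapse = ", "))
    out[miss] <- "UNCHANGED"
  }
  out
}

# MD5 checksum of a file (manifest bookkeeping).
.file_md5 <- function(path) unname(tools::md5sum(path))
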