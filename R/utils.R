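#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Derive an independent child seed (31-bit integer) from a master seed and a
# phase label, so that the topology / date / rate / mutation streams of a
# simulation are reproducible in isolation.
.child_rng <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- rlang::hash(list(as.integer(seed), label))
  (strtoi(substr(h, 1, 7), base = 16L) %% .Machine$integer.max) + 1L
}

# locate the bundled python simulation helper
.engine_script <- function() {
  path <- system.file("python", "sim_engine.py", package = "admixscreen")
  if (!nzchar(path)) stop("bundled python helper not found")
  path
}

.python_bin <- function() {
  bin <- Sys.which("python")
  if (!nzchar(bin)) bin <- Sys.which("python3")
  if (!nzchar(bin)) stop("no python interpreter on PATH; the coalescent engine needs python with msprime")
  bin
}
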