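#' Derive a child RNG seed from a master seed
#'
#' All stochastic operations in modnet consume seeds derived from a single
#' master seed through this splitter, so that a whole pipeline run is
#' reproducible from one integer.  The scheme is a Lehmer step modulo the
#' Mersenne prime 2^31 - 1: `child = (master * 48271 + k) mod (2^31 - 1)`,
#' which keeps every derived seed a valid 32-bit R integer and makes distinct
#' stream indices `k` yield distinct seeds.
#'
#' @param master integer master seed.
#' @param k nonnegative integer stream index.
#' @return an integer seed.
#' @export
#' @examples
#' split_seed(17, 1)
split_seed <- function(master, k) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
  m <- 2147483647
  v <- (abs(master) %% m) * 48271 + k   # < 2^47, exact in a double
  as.integer(v %% m)
}

# Cheap deterministic checksum for run manifests (FNV-1a over the deparsed
# object; not cryptographic, just a fingerprint for audit logs).
config_fingerprint <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
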