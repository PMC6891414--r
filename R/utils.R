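#' @keywords internal
"_PACKAGE"

# Canonical sensor order of the array and the three analytes, used everywhere
# a fixed ordering matters (feature blocks, CSV schemas, model outputs).
ET_SENSORS  <- c("GEC", "CuO", "Cu", "PtNP", "WO3", "Pt")
ET_ANALYTES <- c("diazepam", "flunitrazepam", "lorazepam")

#' Canonical sensor and analyte labels
#'
#' The array order is fixed: bare graphite-epoxy composite (GEC), CuO- and
#' Cu-nanoparticle modified composites, Pt-nanoparticle composite, WO3
#' composite, and a Pt disk. Feature vectors, CSV files and model outputs all
#' use this order.
#'
#' @return Character vector of labels.
#' @export
et_sensors <- function() ET_SENSORS

#' @rdname et_sensors
#' @export
et_analytes <- function() ET_ANALYTES

# Deterministic 32-bit stream seed from a master seed plus arbitrary labels.
# FNV-1a over the UTF-8 bytes of the pasted labels, mixed with the master seed;
# all arithmetic stays below 2^53 so doubles are exact, result is in [0, 2^31).
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  key <- paste(c(format(master), ...), collapse = "\r")
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% 2147483647)
}

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# FNV-1a hash of a character scalar, returned as 8-char hex; used for fixture
# manifests and config stamps (content fingerprint, not cryptographic).
fnv1a_hex <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

stop_et <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "etongue_error")))
}
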