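#' @useDynLib fessemg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

MOTION_LABELS <- c("sitting", "walking", "climbing_stairs",
                   "ankle_dorsiflexion", "ankle_plantarflexion", "cycling")
FATIGUE_LABELS <- c("no_fatigue", "medium", "extreme")
REHAB_MOTIONS <- c("ankle_dorsiflexion", "ankle_plantarflexion", "cycling")

#' Motion and fatigue label sets
#'
#' The six lower-limb motions (three daily tasks, three rehabilitation
#' exercises) and the three Borg-RPE-derived fatigue bands used throughout
#' the package.
#'
#' @return Character vector of labels.
#' @export
motion_labels <- function() MOTION_LABELS

#' @rdname motion_labels
#' @export
fatigue_labels <- function() FATIGUE_LABELS

stop_input <- function(...) stop(..., call. = FALSE)

check_motion <- function(motion) {
  if (!is.character(motion) || length(motion) != 1L || !(motion %in% MOTION_LABELS))
    stop_input("unknown motion label: ", paste(motion, collapse = ","),
               " (expected one of ", paste(MOTION_LABELS, collapse = ", "), ")")
  motion
}

check_fatigue <- function(fatigue) {
  if (!is.character(fatigue) || length(fatigue) != 1L || !(fatigue %in% FATIGUE_LABELS))
    stop_input("unknown fatigue label: ", paste(fatigue, collapse = ","),
               " (expected one of ", paste(FATIGUE_LABELS, collapse = ", "), ")")
  fatigue
}

# Deterministic sub-seed derivation; result always in [1, 2^31 - 2] so it is
# a valid 32-bit R integer seed.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  m <- 2147483647 # 2^31 - 1, prime
  for (p in parts) h <- (h * 48271 + (as.numeric(p) %% m) + 11) %% m
  as.integer(h %% (m - 2) + 1)
}

# Run code under a temporary RNG state so generators are deterministic by
# their own seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
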