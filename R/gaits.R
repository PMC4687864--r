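#' @keywords internal
"_PACKAGE"

LIMBS <- c("LF", "RF", "LH", "RH")

#' Hildebrand footfall timings for one stride
#'
#' A `gait_timings` object describes one stride cycle in Hildebrand's sense:
#' for each limb (LF, RF, LH, RH) the phase of contact onset as a fraction of
#' the stride in `[0, 1)`, the stance fraction (duty factor) in `(0, 1)`, and
#' the stride period in seconds. Phases are anchored at the first hind contact
#' by convention; anchoring only affects presentation, never pairwise phase
#' differences.
#'
#' @param contact_onset named numeric, onset phase per limb in `[0, 1)`.
#'   Names must be `LF`, `RF`, `LH`, `RH`.
#' @param stance_fraction named numeric (or scalar, recycled), per-limb duty
#'   factor in `(0, 1)`.
#' @param stride_period stride duration in seconds, `> 0`.
#' @return an object of class `gait_timings`.
#' @examples
#' trot <- gait_timings(c(LF = 0.5, RF = 0, LH = 0, RH = 0.5), 0.4, 0.15)
#' phase_differences(trot)
#' @export
gait_timings <- function(contact_onset, stance_fraction, stride_period) {
  if (length(stance_fraction) == 1L) {
    stance_fraction <- stats::setNames(rep(stance_fraction, 4L), LIMBS)
  }
  missing <- setdiff(LIMBS, names(contact_onset))
  if (length(missing)) {
    stop("missing limb(s) in contact_onset: ", paste(missing, collapse = ", "))
  }
  missing <- setdiff(LIMBS, names(stance_fraction))
  if (length(missing)) {
    stop("missing limb(s) in stance_fraction: ", paste(missing, collapse = ", "))
  }
  contact_onset <- contact_onset[LIMBS]
  stance_fraction <- stance_fraction[LIMBS]
  if (any(contact_onset < 0 | contact_onset >= 1)) {
    stop("contact onset phases must lie in [0, 1)")
  }
  if (any(stance_fraction <= 0 | stance_fraction >= 1)) {
    stop("stance fractions must lie in (0, 1)")
  }
  if (!is.numeric(stride_period) || length(stride_period) != 1L ||
      stride_period <= 0) {
    stop("stride_period must be a single positive number (seconds)")
  }
  structure(
    list(contact_onset = contact_onset,
         stance_fraction = stance_fraction,
         stride_period = stride_period),
    class = "gait_timings")
}

#' @export
print.gait_timings <- function(x, ...) {
  cat("Hildebrand gait timings (stride", format(x$stride_period), "s)\n")
  print(data.frame(limb = LIMBS,
                   onset_phase = unname(x$contact_onset),
                   stance_fraction = unname(x$stance_fraction)),
        row.names = FALSE)
  invisible(x)
}

## circular distance between two stride phases, folded into [0, 0.5]
circular_phase_distance <- function(a, b) {
  d <- abs(a - b) %% 1
  pmin(d, 1 - d)
}

#' Hildebrand pair phase differences F, R, D1, D2
#'
#' Computes the circular phase distance (as a fraction of stride, folded into
#' `[0, 0.5]`) between the limbs of each named pair: `F` fore pair (LF, RF),
#' `R` hind pair (LH, RH), `D1` diagonal pair (LF, RH) and `D2` diagonal pair
#' (RF, LH). Symmetric gaits such as trot have `F = R = 0.5` and small
#' diagonal differences; in asymmetric gaits the hind pair difference
#' collapses towards zero.
#'
#' @param timings a [gait_timings()] object.
#' @return named numeric vector with elements `F`, `R`, `D1`, `D2`.
#' @export
phase_differences <- function(timings) {
  stopifnot(inherits(timings, "gait_timings"))
  on <- timings$contact_onset
  c(F  = circular_phase_distance(on[["LF"]], on[["RF"]]),
    R  = circular_phase_distance(on[["LH"]], on[["RH"]]),
    D1 = circular_phase_distance(on[["LF"]], on[["RH"]]),
    D2 = circular_phase_distance(on[["RF"]], on[["LH"]]))
}

#' Timing asymmetry index T_diff
#'
#' `T_diff = R - max(D1, D2)`, as a proportion of stride duration. Positive
#' for trot-like timing (hind pair out of phase, diagonals synchronised),
#' negative for bound-like timing (hind pair in phase).
#'
#' @inheritParams phase_differences
#' @return a single number in `[-0.5, 0.5]`.
#' @export
t_diff <- function(timings) {
  pd <- phase_differences(timings)
  unname(pd[["R"]] - max(pd[["D1"]], pd[["D2"]]))
}

#' Rule-based gait labelling from footfall onsets
#'
#' Applies the footfall-timing rules used for manual video classification:
#' the gait is a trot when the smallest pairwise onset difference is between a
#' diagonal pair of legs, a gallop or half-bound when it is between the fore
#' or hind pair (a half-bound when additionally the hind feet land within
#' `hind_sync_s` of each other), and a creep when diagonal-pair and
#' fore/hind-pair differences are similar (within `creep_tol` of the stride
#' period).
#'
#' @param contact_onsets named numeric, one onset time in seconds per limb
#'   (`LF`, `RF`, `LH`, `RH`) within one stride.
#' @param stride_period stride duration in seconds, `> 0`.
#' @param hind_sync_s hind-pair synchrony bound distinguishing half-bound
#'   from gallop (seconds; default 0.025).
#' @param creep_tol "similar timings" tolerance for the creep rule, as a
#'   fraction of stride period (default 0.08).
#' @return a `gait_label` object: list with `category` (one of `creep`,
#'   `trot`, `gallop`, `half_bound`) and `symmetric_flag` (Hildebrand sense).
#' @export
label_gait <- function(contact_onsets, stride_period,
                       hind_sync_s = 0.025, creep_tol = 0.08) {
  if (!is.numeric(stride_period) || stride_period <= 0) {
    stop("stride_period must be positive")
  }
  missing <- setdiff(LIMBS, names(contact_onsets))
  if (length(missing)) {
    stop("missing limb(s): ", paste(missing, collapse = ", "))
  }
  on <- contact_onsets[LIMBS]
  ## circular onset distance in seconds within the stride cycle
  dist_s <- function(a, b) {
    d <- abs(a - b) %% stride_period
    min(d, stride_period - d)
  }
  d_fore <- dist_s(on[["LF"]], on[["RF"]])
  d_hind <- dist_s(on[["LH"]], on[["RH"]])
  d_diag <- min(dist_s(on[["LF"]], on[["RH"]]), dist_s(on[["RF"]], on[["LH"]]))
  d_pair <- min(d_fore, d_hind)

  if (abs(d_diag - d_pair) < creep_tol * stride_period) {
    category <- "creep"
  } else if (d_diag < d_pair) {
    category <- "trot"
  } else if (d_hind < hind_sync_s) {
    category <- "half_bound"
  } else {
    category <- "gallop"
  }
  gait_label(category)
}

#' @rdname label_gait
#' @param category gait category string.
#' @export
gait_label <- function(category = c("creep", "trot", "gallop", "half_bound")) {
  category <- match.arg(category)
  structure(list(category = category,
                 symmetric_flag = category %in% c("creep", "trot")),
            class = "gait_label")
}

#' @export
print.gait_label <- function(x, ...) {
  cat(sprintf("gait: %s (%s)\n", x$category,
              if (x$symmetric_flag) "symmetric" else "asymmetric"))
  invisible(x)
}

#' Canonical gait library
#'
#' Idealised Hildebrand timings for the four gait categories observed on the
#' wheel, at a given stride period and duty factor. The trot synchronises
#' diagonal pairs half a stride apart; the half-bound lands both hind feet
#' together with the fore contacts at 0.45 and 0.70 of the stride (so at
#' running duty factors each limb's stance clears the next hind contact);
#' the gallop splits the hind pair by 0.18 strides; the creep spreads all
#' four contacts so that diagonal and girdle-pair timing differences are
#' similar.
#'
#' @param gait gait category.
#' @param stride_period stride duration, seconds.
#' @param duty_factor per-limb stance fraction in `(0, 1)`.
#' @return a [gait_timings()] object.
#' @export
canonical_gait <- function(gait = c("trot", "half_bound", "gallop", "creep"),
                           stride_period = 0.15, duty_factor = 0.4) {
  gait <- match.arg(gait)
  phases <- switch(gait,
    trot       = c(LF = 0.5,  RF = 0,    LH = 0,   RH = 0.5),
    half_bound = c(LF = 0.45, RF = 0.70, LH = 0,   RH = 0),
    gallop     = c(LF = 0.50, RF = 0.73, LH = 0,   RH = 0.18),
    creep      = c(LF = 0.55, RF = 0.80, LH = 0,   RH = 0.30))
  gait_timings(phases, duty_factor, stride_period)
}

#' Froude-number dynamic-similarity model
#'
#' @param leg_length hip height `L` in metres (`> 0`; default 0.026 for a
#'   typical adult mouse).
#' @param gravity gravitational acceleration in m/s^2 (default 9.81).
#' @param transition_froude named numeric: Froude numbers of the walk-trot
#'   band (lower/upper) and the trot-gallop transition. Defaults 0.5, 1, 1.8.
#' @return a `froude_model` object.
#' @export
froude_model <- function(leg_length = 0.026, gravity = 9.81,
                         transition_froude = c(walk_trot_low = 0.5,
                                               walk_trot_high = 1.0,
                                               trot_gallop = 1.8)) {
  if (leg_length <= 0) stop("leg_length must be positive")
  if (gravity <= 0) stop("gravity must be positive")
  if (any(transition_froude <= 0) || is.unsorted(transition_froude)) {
    stop("transition Froude numbers must be positive and increasing")
  }
  structure(list(leg_length = leg_length, gravity = gravity,
                 transition_froude = transition_froude),
            class = "froude_model")
}

#' Froude number of a speed
#'
#' `Fr = V^2 / (g L)`, the dimensionless speed used to compare locomotion
#' across animals of different size.
#'
#' @param speed speed `V` in m/s (`>= 0`).
#' @param model a [froude_model()].
#' @return dimensionless Froude number.
#' @export
froude_number <- function(speed, model = froude_model()) {
  stopifnot(inherits(model, "froude_model"))
  if (any(speed < 0)) stop("speed must be non-negative")
  speed^2 / (model$gravity * model$leg_length)
}

#' Predicted gait-transition speeds from dynamic similarity
#'
#' Inverts the Froude relation, `V = sqrt(Fr g L)`, at each transition Froude
#' number of the model. For a mouse with hip height 2.6 cm the defaults give
#' a walk-trot band of 0.36-0.51 m/s and a trot-gallop transition at
#' 0.68 m/s.
#'
#' @param model a [froude_model()].
#' @return named numeric vector of speeds in m/s.
#' @export
predict_transition_speeds <- function(model = froude_model()) {
  stopifnot(inherits(model, "froude_model"))
  sqrt(model$transition_froude * model$gravity * model$leg_length)
}

#' Read a footfall annotation table
#'
#' Reads a delimited text table of per-limb contact annotations (as produced
#' from high-speed video), with columns `limb`, `onset_s`, `offset_s`,
#' `stride_id`, and converts each stride into a [gait_timings()] object.
#'
#' @param path path to a CSV/TSV file (delimiter inferred from extension).
#' @return named list of `gait_timings`, one per stride id.
#' @export
read_footfall_annotations <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("limb", "onset_s", "offset_s", "stride_id")
  if (!all(need %in% names(tab))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(tab, tab$stride_id), function(s) {
    if (!setequal(s$limb, LIMBS)) {
      stop("stride ", s$stride_id[1], " does not have one row per limb")
    }
    s <- s[match(LIMBS, s$limb), ]
    t0 <- min(s$onset_s[s$limb %in% c("LH", "RH")])
    period <- max(s$offset_s) - min(s$onset_s)
    ## stride period from annotation span; phases anchored at first hind onset
    onset <- ((s$onset_s - t0) / period) %% 1
    stance <- (s$offset_s - s$onset_s) / period
    gait_timings(stats::setNames(onset, s$limb),
                 stats::setNames(pmin(pmax(stance, 1e-6), 1 - 1e-6), s$limb),
                 period)
  })
  out
}

#' Serialise / read a gait library as JSON
#'
#' @param gaits named list of [gait_timings()] objects.
#' @param path output (input) JSON path.
#' @return `write_gait_library` returns `path` invisibly;
#'   `read_gait_library` returns a named list of `gait_timings`.
#' @export
write_gait_library <- function(gaits, path) {
  payload <- lapply(gaits, function(g) {
    list(contact_onset = as.list(g$contact_onset),
         stance_fraction = as.list(g$stance_fraction),
         stride_period = g$stride_period)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gait_library
#' @export
read_gait_library <- function(path) {
  payload <- jsonlite::read_json(path)
  lapply(payload, function(g) {
    gait_timings(unlist(g$contact_onset), unlist(g$stance_fraction),
                 g$stride_period)
  })
}
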