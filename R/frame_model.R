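#' @title Frame records: domain types for snapshot photophysics
#' @description Constructors and validators for the per-snapshot records the
#'   pipeline consumes: excited states (energy, transition dipole moment,
#'   two-photon strength), first-hyperpolarizability tensors, and the frame
#'   itself (geometry descriptors plus the excited-state set).
#' @name frame_model
NULL

#' Create an excited-state record
#'
#' @param state_index integer state label, 1 = S1.
#' @param excitation_energy vertical excitation energy in eV (> 0).
#' @param tdm transition dipole moment, length-3 numeric, atomic units,
#'   lab frame.
#' @param tpa_strength_delta two-photon transition strength delta in atomic
#'   units (>= 0).
#' @return an object of class `excited_state`.
#' @export
excited_state <- function(state_index, excitation_energy, tdm,
                          tpa_strength_delta = 0) {
  s <- list(state_index = as.integer(state_index),
            excitation_energy = as.numeric(excitation_energy),
            tdm = as.numeric(tdm),
            tpa_strength_delta = as.numeric(tpa_strength_delta))
  class(s) <- "excited_state"
  validate_excited_state(s)
  s
}

validate_excited_state <- function(s) {
  if (length(s$state_index) != 1 || is.na(s$state_index) || s$state_index < 1)
    stop("state_index must be a single integer >= 1")
  if (length(s$excitation_energy) != 1 || !is.finite(s$excitation_energy) ||
      s$excitation_energy <= 0)
    stop("excitation_energy must be a single finite value > 0 (eV)")
  if (length(s$tdm) != 3 || any(!is.finite(s$tdm)))
    stop("tdm must have 3 finite components")
  if (!is.finite(s$tpa_strength_delta) || s$tpa_strength_delta < 0)
    stop("tpa_strength_delta must be finite and >= 0")
  invisible(s)
}

#' Create a first-hyperpolarizability tensor
#'
#' The 27 molecular-frame components beta_ijk in atomic units.  `components`
#' may be a 3x3x3 array or a length-27 vector in R column-major order
#' (index i varying fastest).
#'
#' @param components 3x3x3 array or length-27 numeric.
#' @param regime `"static"` (zero-frequency) or `"dynamic"` (frequency-
#'   dependent; requires `wavelength`).
#' @param wavelength impinging wavelength in nm for the dynamic regime
#'   (conventionally 810 nm); `NULL` for static.
#' @return an object of class `beta_tensor` (a 3x3x3 array with attributes).
#' @export
beta_tensor <- function(components, regime = c("static", "dynamic"),
                        wavelength = NULL) {
  regime <- match.arg(regime)
  b <- array(as.numeric(components), dim = c(3, 3, 3))
  if (length(components) != 27 || any(!is.finite(b)))
    stop("beta tensor needs exactly 27 finite components")
  if (regime == "dynamic") {
    if (is.null(wavelength) || !is.finite(wavelength) || wavelength <= 0)
      stop("dynamic beta tensor requires a wavelength > 0 (nm)")
    attr(b, "wavelength") <- as.numeric(wavelength)
  }
  attr(b, "regime") <- regime
  class(b) <- c("beta_tensor", "array")
  b
}

#' Create a frame record
#'
#' One snapshot of the probe in its membrane: geometry descriptors plus the
#' excited-state manifold and hyperpolarizability tensors.
#'
#' @param frame_id integer >= 1.
#' @param time frame time in ns (>= 0).
#' @param phase phase label (`"DOPC"`, `"DPPC"`, `"SMCHOL"` or custom).
#' @param membrane_normal unit 3-vector; by convention the lab +z axis.
#' @param depth probe center-of-mass distance from the phosphorus plane, nm.
#' @param dihedrals 7 backbone dihedral angles in degrees, in (-180, 180].
#' @param states list of [excited_state] objects sorted by state index.
#' @param beta_static static [beta_tensor] (optional, may be `NULL`).
#' @param beta_dynamic dynamic [beta_tensor] (optional).
#' @return an object of class `frame_record`.
#' @export
frame_record <- function(frame_id, time, phase, membrane_normal, depth,
                         dihedrals, states, beta_static = NULL,
                         beta_dynamic = NULL) {
  fr <- list(frame_id = as.integer(frame_id), time = as.numeric(time),
             phase = as.character(phase),
             membrane_normal = as.numeric(membrane_normal),
             depth = as.numeric(depth), dihedrals = as.numeric(dihedrals),
             states = states, beta_static = beta_static,
             beta_dynamic = beta_dynamic)
  class(fr) <- "frame_record"
  validate_frame_record(fr)
  fr
}

validate_frame_record <- function(fr) {
  if (length(fr$frame_id) != 1 || is.na(fr$frame_id) || fr$frame_id < 1)
    stop("frame_id must be a single integer >= 1")
  if (!is.finite(fr$time) || fr$time < 0)
    stop("time must be finite and >= 0 (ns)")
  n <- fr$membrane_normal
  if (length(n) != 3 || any(!is.finite(n)) ||
      abs(sqrt(sum(n^2)) - 1) > 1e-9)
    stop("membrane_normal must be a unit 3-vector (|n| = 1 within 1e-9)")
  if (length(fr$dihedrals) != 7)
    stop("dihedrals must contain exactly 7 angles (dh1..dh7)")
  if (any(!is.finite(fr$dihedrals)) ||
      any(fr$dihedrals <= -180 - 1e-9 | fr$dihedrals > 180 + 1e-9))
    stop("dihedral angles must lie in (-180, 180] degrees")
  if (!is.finite(fr$depth)) stop("depth must be finite (nm)")
  if (!is.list(fr$states) || length(fr$states) < 1)
    stop("states must be a non-empty list of excited_state records")
  idx <- vapply(fr$states, function(s) s$state_index, integer(1))
  if (is.unsorted(idx, strictly = TRUE))
    stop("states must be sorted by strictly increasing state_index")
  lapply(fr$states, validate_excited_state)
  for (b in list(fr$beta_static, fr$beta_dynamic)) {
    if (!is.null(b) && !inherits(b, "beta_tensor"))
      stop("beta_static/beta_dynamic must be beta_tensor objects or NULL")
  }
  invisible(fr)
}

#' @export
print.frame_record <- function(x, ...) {
  cat(sprintf("<frame_record %d> phase=%s t=%.3f ns depth=%.3f nm, %d states%s\n",
              x$frame_id, x$phase, x$time, x$depth, length(x$states),
              if (!is.null(x$beta_dynamic)) ", static+dynamic beta"
              else if (!is.null(x$beta_static)) ", static beta" else ""))
  invisible(x)
}

state_by_index <- function(fr, state_index) {
  for (s in fr$states) if (s$state_index == state_index) return(s)
  NULL
}

frame_to_list <- function(fr) {
  out <- list(frame_id = fr$frame_id, time = fr$time, phase = fr$phase,
              membrane_normal = fr$membrane_normal, depth = fr$depth,
              dihedrals = fr$dihedrals,
              states = lapply(fr$states, function(s) {
                list(state_index = s$state_index,
                     excitation_energy = s$excitation_energy,
                     tdm = s$tdm,
                     tpa_strength_delta = s$tpa_strength_delta)
              }))
  beta_to_list <- function(b) {
    if (is.null(b)) return(NULL)
    l <- list(components = as.numeric(b), regime = attr(b, "regime"))
    if (!is.null(attr(b, "wavelength"))) l$wavelength <- attr(b, "wavelength")
    l
  }
  out$beta_static <- beta_to_list(fr$beta_static)
  out$beta_dynamic <- beta_to_list(fr$beta_dynamic)
  out[!vapply(out, is.null, logical(1))]
}

list_to_frame <- function(l) {
  states <- lapply(l$states, function(s) {
    excited_state(s$state_index, s$excitation_energy, unlist(s$tdm),
                  if (is.null(s$tpa_strength_delta)) 0 else s$tpa_strength_delta)
  })
  beta_from_list <- function(b) {
    if (is.null(b)) return(NULL)
    beta_tensor(unlist(b$components), regime = b$regime,
                wavelength = b$wavelength)
  }
  frame_record(l$frame_id, l$time, l$phase, unlist(l$membrane_normal),
               l$depth, unlist(l$dihedrals), states,
               beta_static = beta_from_list(l$beta_static),
               beta_dynamic = beta_from_list(l$beta_dynamic))
}

#' Read frame records from a JSON-Lines file
#'
#' One frame per line, UTF-8, keys as in [frame_record()].  In strict mode
#' any malformed line or invariant violation is an error naming the line
#' (and frame id where available); in lenient mode offending lines are
#' skipped with a warning reporting how many were dropped.
#'
#' @param path path to a `.jsonl` frames file.
#' @param strict logical; reject (`TRUE`, default) or skip-and-warn.
#' @return a list of `frame_record` objects, file order preserved.  The
#'   number of skipped lines (lenient mode) is attached as attribute
#'   `"skipped"`.
#' @export
read_frames <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("frames file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("frames file is empty: ", path)
    out <- list()
    attr(out, "skipped") <- 0L
    return(out)
  }
  frames <- vector("list", length(lines))
  keep <- logical(length(lines))
  n_skipped <- 0L
  for (i in seq_along(lines)) {
    fr <- tryCatch({
      l <- jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE)
      list_to_frame(l)
    }, error = function(e) e)
    if (inherits(fr, "error")) {
      msg <- sprintf("line %d: %s", i, conditionMessage(fr))
      if (strict) stop("invalid frame record at ", msg) else {
        n_skipped <- n_skipped + 1L
        next
      }
    }
    frames[[i]] <- fr
    keep[i] <- TRUE
  }
  if (n_skipped > 0)
    warning(sprintf("skipped %d invalid line(s) in %s", n_skipped, path))
  out <- frames[keep]
  attr(out, "skipped") <- n_skipped
  out
}

#' Write frame records to a JSON-Lines file
#'
#' Numbers are serialized at full double precision so that
#' `read_frames(write_frames(x))` round-trips every numeric field to
#' better than 1e-12 relative.
#'
#' @param frames list of `frame_record` objects.
#' @param path output path.
#' @return invisibly, the number of records written.
#' @export
write_frames <- function(frames, path) {
  lapply(frames, validate_frame_record)
  lines <- vapply(frames, function(fr) {
    as.character(jsonlite::toJSON(frame_to_list(fr), auto_unbox = TRUE,
                                  digits = NA))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, useBytes = TRUE)
  invisible(length(lines))
}

#' Per-phase optical configuration
#'
#' Refractive index and temperature per membrane phase.  The built-in
#' defaults are n = 1.378 (DOPC, liquid-disordered), 1.789 (DPPC, solid
#' gel), 1.555 (2:1 SM/Chol, liquid-ordered), all at 298 K.
#'
#' @param path optional YAML file with entries
#'   `phases: {LABEL: {refractive_index: x, temperature: y}}`; entries
#'   override/extend the defaults.
#' @return data.frame with columns `phase`, `refractive_index`,
#'   `temperature`.
#' @export
#' @examples
#' phase_config()
phase_config <- function(path = NULL) {
  cfg <- data.frame(phase = c("DOPC", "DPPC", "SMCHOL"),
                    refractive_index = c(1.378, 1.789, 1.555),
                    temperature = c(298, 298, 298),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    ph <- if (!is.null(y$phases)) y$phases else y
    for (label in names(ph)) {
      e <- ph[[label]]
      n <- e$refractive_index
      temp <- if (is.null(e$temperature)) 298 else e$temperature
      if (is.null(n)) stop("phase config for '", label,
                           "' lacks refractive_index")
      if (!is.finite(n) || n < 1) stop("refractive_index for '", label,
                                       "' must be >= 1")
      if (!is.finite(temp) || temp <= 0) stop("temperature for '", label,
                                              "' must be > 0 (K)")
      i <- match(toupper(label), cfg$phase)
      if (is.na(i)) {
        cfg <- rbind(cfg, data.frame(phase = toupper(label),
                                     refractive_index = n,
                                     temperature = temp))
      } else {
        cfg$refractive_index[i] <- n
        cfg$temperature[i] <- temp
      }
    }
  }
  cfg
}

phase_refractive_index <- function(config, phase) {
  i <- match(toupper(phase), config$phase)
  if (is.na(i)) stop("no refractive index configured for phase '", phase, "'")
  config$refractive_index[i]
}
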