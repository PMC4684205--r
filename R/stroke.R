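# The 26-parameter periodic stroke model.
#
# Each limb-pair joint has three degrees of freedom: dorsoventral (dv,
# positive dorsal), anteroposterior (ap, positive anterior) and long-axis
# rotation (rot, positive supination).  Each DOF follows a modified
# sinusoid described by its minimum, maximum and phase; each sinusoid
# additionally carries a downstroke/upstroke time asymmetry, and each limb
# pair's rotation DOF a motionless hold interval.  With left/right
# synchrony that is 2 x (9 sinusoid values + 3 asymmetries) + 2 holds = 26
# free values; the frequency is fixed at 0.5 Hz for every sinusoid.

STROKE_FREQUENCY <- 0.5  # Hz, fixed for all sinusoids

#' One modified-sinusoid DOF specification
#'
#' @param min_angle,max_angle Extremes of the sinusoid in degrees.
#' @param phase Phase as a fraction of the period in `[0, 1)`.
#' @param asym Downstroke/upstroke time asymmetry in (0, 1); values above
#'   0.5 make the stroke toward the ventral/pronate/posterior extreme (the
#'   minimum angle) faster than the return.
#' @return A `psw_sinusoid` list.
#' @export
sinusoid_spec <- function(min_angle, max_angle, phase = 0, asym = 0.5) {
  stopifnot(min_angle <= max_angle, asym > 0, asym < 1)
  structure(list(min = min_angle, max = max_angle,
                 phase = phase %% 1, asym = asym),
            class = "psw_sinusoid")
}

#' Stroke of one limb pair
#'
#' @param dv,ap,rot [sinusoid_spec()]s for the dorsoventral,
#'   anteroposterior and rotation components.
#' @param rotation_hold Motionless rotation interval per cycle in seconds,
#'   split equally between the supinated and pronated extremes.
#' @param period Stroke period in seconds (for validation only).
#' @return A `psw_limb_stroke` list.
#' @export
limb_stroke <- function(dv, ap, rot, rotation_hold = 0,
                        period = 1 / STROKE_FREQUENCY) {
  stopifnot(rotation_hold >= 0, rotation_hold < period)
  structure(list(dv = dv, ap = ap, rot = rot, hold = rotation_hold),
            class = "psw_limb_stroke")
}

#' Full 26-parameter stroke description
#'
#' @param fore,hind [limb_stroke()]s for the fore and hind limb pairs
#'   (left and right limbs move in synchrony).
#' @return A `psw_stroke` list; `frequency` is fixed at 0.5 Hz and is not a
#'   free parameter.
#' @export
stroke_params <- function(fore, hind) {
  structure(list(fore = fore, hind = hind, frequency = STROKE_FREQUENCY),
            class = "psw_stroke")
}

#' Load a joint-range preset
#'
#' Presets (`narrow`, `medium`, `wide`) bound the dorsoventral and
#' anteroposterior sinusoid extremes per limb pair; the rotation range
#' (+30 supination / -45 pronation) and the neutral poses (forelimb -15
#' dorsoventral / -16 anteroposterior, hindlimb -30 / -27) are shared by
#' all presets.  Values are read from an editable JSON file.
#'
#' @param name Preset name: "narrow", "medium" or "wide".
#' @param file Optional path to an alternative preset file.
#' @return A `psw_preset` list with per-limb `dv`, `ap`, `rot` bounds and
#'   `neutral` / `abducted` poses (degrees).
#' @export
joint_presets <- function(name = c("medium", "narrow", "wide"), file = NULL) {
  name <- match.arg(name)
  if (is.null(file))
    file <- system.file("extdata", "joint_ranges.json", package = "plesioswim")
  cfg <- jsonlite::fromJSON(file)
  pr <- cfg$presets[[name]]
  rot <- c(cfg$rotation$min, cfg$rotation$max)
  limbs <- lapply(c(fore = "fore", hind = "hind"), function(lb) {
    list(dv = as.numeric(pr[[lb]]$dv), ap = as.numeric(pr[[lb]]$ap),
         rot = rot)
  })
  neutral <- lapply(c(fore = "fore", hind = "hind"), function(lb) {
    nn <- cfg$neutral[[lb]]
    c(dv = nn$dv, ap = nn$ap, rot = nn$rot)
  })
  abducted <- lapply(c(fore = "fore", hind = "hind"), function(lb) {
    c(dv = limbs[[lb]]$dv[2], ap = neutral[[lb]][["ap"]], rot = 0)
  })
  structure(list(name = name, fore = limbs$fore, hind = limbs$hind,
                 neutral = neutral, abducted = abducted),
            class = "psw_preset")
}

# flat layout of one limb pair: 13 values
.limb_layout <- c("dv.min", "dv.max", "dv.phase", "ap.min", "ap.max",
                  "ap.phase", "rot.min", "rot.max", "rot.phase", "dv.asym",
                  "ap.asym", "rot.asym", "hold")

#' Encode stroke parameters as the flat 26-vector
#'
#' Layout: 13 values per limb pair (fore then hind):
#' `dv.min, dv.max, dv.phase, ap.min, ap.max, ap.phase, rot.min, rot.max,
#' rot.phase, dv.asym, ap.asym, rot.asym, hold`.
#'
#' @param params A [stroke_params()].
#' @return Named numeric vector of length 26.
#' @export
encode_stroke <- function(params) {
  one <- function(ls) {
    c(ls$dv$min, ls$dv$max, ls$dv$phase, ls$ap$min, ls$ap$max, ls$ap$phase,
      ls$rot$min, ls$rot$max, ls$rot$phase, ls$dv$asym, ls$ap$asym,
      ls$rot$asym, ls$hold)
  }
  v <- c(one(params$fore), one(params$hind))
  names(v) <- c(paste0("fore.", .limb_layout), paste0("hind.", .limb_layout))
  v
}

#' Decode a flat 26-vector into stroke parameters
#'
#' Angles are clamped into the active preset's bounds (with a warning and a
#' swap if a clamped minimum exceeds its maximum), phases are wrapped into
#' `[0, 1)`, asymmetries clamped to `[0.05, 0.95]` and holds to
#' `[0, 0.95 * period]`.  Clamping is idempotent.
#'
#' @param v Numeric vector of length 26 (see [encode_stroke()] layout).
#' @param preset A [joint_presets()] giving the active bounds.
#' @param warn Warn when a clamped minimum exceeds its maximum (the pair
#'   is swapped either way).
#' @return A [stroke_params()].
#' @export
decode_stroke <- function(v, preset = joint_presets("medium"), warn = TRUE) {
  if (length(v) != 26) stop("stroke vector must have length 26, got ",
                            length(v))
  period <- 1 / STROKE_FREQUENCY
  one <- function(x, bounds) {
    dof <- function(mn, mx, ph, a, bd) {
      mn2 <- min(max(mn, bd[1]), bd[2])
      mx2 <- min(max(mx, bd[1]), bd[2])
      if (mn2 > mx2) {
        if (warn) warning("sinusoid min exceeds max after clamping; swapping")
        tmp <- mn2; mn2 <- mx2; mx2 <- tmp
      }
      sinusoid_spec(mn2, mx2, ph %% 1, min(max(a, 0.05), 0.95))
    }
    limb_stroke(
      dv = dof(x[1], x[2], x[3], x[10], bounds$dv),
      ap = dof(x[4], x[5], x[6], x[11], bounds$ap),
      rot = dof(x[7], x[8], x[9], x[12], bounds$rot),
      rotation_hold = min(max(x[13], 0), 0.95 * period))
  }
  stroke_params(fore = one(unname(v[1:13]), preset$fore),
                hind = one(unname(v[14:26]), preset$hind))
}

#' Piecewise-linear time warp implementing stroke time asymmetry
#'
#' Maps cycle phase so that the half-cycle sweeping toward the
#' ventral/pronate/posterior extreme occupies `(1 - a)` of the period and
#' the return half occupies `a`: asymmetries above 0.5 give a faster power
#' stroke.  The warp is a monotone bijection of the cycle onto itself with
#' the extremes as fixed points.
#'
#' @param a Asymmetry in (0, 1).
#' @param t Time in seconds (vectorized).
#' @param period Cycle period in seconds.
#' @return Warped phase in `[0, 1)`, where phase 0 is the maximum of the
#'   underlying cosine and phase 0.5 its minimum.
#' @export
warp_time <- function(a, t, period = 1 / STROKE_FREQUENCY) {
  if (a <= 0 || a >= 1) stop("asymmetry must lie strictly inside (0, 1)")
  x <- (t / period) %% 1
  ifelse(x < 1 - a, 0.5 * x / (1 - a), 0.5 + 0.5 * (x - (1 - a)) / a)
}

#' Evaluate one modified-sinusoid DOF
#'
#' With zero hold and symmetric timing this is exactly
#' `mid + amp * sin(2*pi*(t/period + phase))`.  A positive hold keeps the
#' signal flat for `hold/2` seconds at each extreme and compresses the two
#' sweeps into the remaining `period - hold`; the time asymmetry then
#' divides the sweep time between the descending (power) and ascending
#' (recovery) half-cycles.  The signal is continuous, exactly periodic, and
#' attains its stated extremes.
#'
#' @param spec A [sinusoid_spec()].
#' @param hold Motionless interval per cycle in seconds (rotation DOFs
#'   only; 0 otherwise).
#' @param t Time in seconds (vectorized).
#' @param period Cycle period in seconds.
#' @return Angle in degrees.
#' @export
eval_dof <- function(spec, hold = 0, t, period = 1 / STROKE_FREQUENCY) {
  if (hold >= period) stop("hold must be smaller than the period")
  mid <- (spec$min + spec$max) / 2
  amp <- (spec$max - spec$min) / 2
  a <- spec$asym
  # cycle coordinate with the maximum at x = 0 (so that the a = 0.5,
  # hold = 0 case reduces to sin(2*pi*(t/period + phase)))
  x <- (t / period + spec$phase - 0.25) %% 1
  H <- (hold / 2) / period          # plateau length per extreme, in phase
  D1 <- (1 - a) * (1 - 2 * H)       # descending (power) sweep
  D2 <- a * (1 - 2 * H)             # ascending (recovery) sweep
  ang <- numeric(length(x))
  seg1 <- x < H / 2                                  # max plateau (start)
  seg2 <- !seg1 & x < H / 2 + D1                     # descending
  seg3 <- !seg1 & !seg2 & x < H / 2 + D1 + H         # min plateau
  seg4 <- !seg1 & !seg2 & !seg3 & x < 1 - H / 2      # ascending
  seg5 <- !(seg1 | seg2 | seg3 | seg4)               # max plateau (end)
  ang[seg1 | seg5] <- 1
  u <- (x[seg2] - H / 2) / D1
  ang[seg2] <- cos(pi * u)
  ang[seg3] <- -1
  u <- (x[seg4] - (H / 2 + D1 + H)) / D2
  ang[seg4] <- cos(pi * (1 + u))
  mid + amp * ang
}

#' Joint target angles for all four limbs at a given time
#'
#' Left and right limbs move in synchrony (mirrored about the sagittal
#' plane); the returned angles are anatomical, i.e. identical for the left
#' and right members of a pair.  Inactive limb pairs are locked at the
#' neutral pose.
#'
#' @param params A [stroke_params()].
#' @param t Time in seconds (scalar).
#' @param active_limbs "all", "fore" or "hind".
#' @param preset A [joint_presets()] supplying the neutral poses.
#' @return Named 12-vector of angles in degrees, ordered
#'   `fore_left.(dv, ap, rot)`, `fore_right.(...)`, `hind_left.(...)`,
#'   `hind_right.(...)`.
#' @export
joint_targets <- function(params, t, active_limbs = "all",
                          preset = joint_presets("medium")) {
  stopifnot(active_limbs %in% c("all", "fore", "hind"))
  period <- 1 / params$frequency
  one_pair <- function(ls, which_limb) {
    if (active_limbs != "all" && active_limbs != which_limb) {
      nn <- preset$neutral[[which_limb]]
      return(c(nn[["dv"]], nn[["ap"]], nn[["rot"]]))
    }
    c(eval_dof(ls$dv, 0, t, period),
      eval_dof(ls$ap, 0, t, period),
      eval_dof(ls$rot, ls$hold, t, period))
  }
  fore <- one_pair(params$fore, "fore")
  hind <- one_pair(params$hind, "hind")
  out <- c(fore, fore, hind, hind)
  names(out) <- paste0(rep(c("fore_left", "fore_right", "hind_left",
                             "hind_right"), each = 3),
                       ".", rep(c("dv", "ap", "rot"), 4))
  out
}

#' A neutral (zero-amplitude) stroke holding the limbs at given poses
#'
#' @param preset A [joint_presets()].
#' @return A [stroke_params()] whose sinusoids have `min = max` at the
#'   neutral pose: the limbs do not move.
#' @export
neutral_stroke <- function(preset = joint_presets("medium")) {
  one <- function(lb) {
    nn <- preset$neutral[[lb]]
    limb_stroke(
      dv = sinusoid_spec(nn[["dv"]], nn[["dv"]]),
      ap = sinusoid_spec(nn[["ap"]], nn[["ap"]]),
      rot = sinusoid_spec(nn[["rot"]], nn[["rot"]]))
  }
  stroke_params(fore = one("fore"), hind = one("hind"))
}

#' Write / read a stroke vector as JSON
#'
#' @param v Named 26-vector (see [encode_stroke()]).
#' @param path File path.
#' @return `read_stroke` returns the named numeric vector.
#' @export
write_stroke <- function(v, path) {
  jsonlite::write_json(as.list(v), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stroke
#' @export
read_stroke <- function(path) {
  unlist(jsonlite::fromJSON(path))
}
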