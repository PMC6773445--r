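# Canonical internal units: length um, time hr, pressure Pa, volume pl.
# 1 pl = 1e3 um^3; conversions happen only at interfaces that are
# explicitly documented to take other units (e.g. Rdot in um/s).
UM3_PER_PL <- 1e3
SEC_PER_HR <- 3600

abort_bad_arg <- function(msg, class = "otomorph_error") {
  rlang::abort(msg, class = class)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_na = FALSE) {
  if (!is.numeric(x)) {
    abort_bad_arg(sprintf("`%s` must be numeric.", name))
  }
  if (!allow_na && anyNA(x)) {
    abort_bad_arg(sprintf("`%s` must not contain missing values.", name))
  }
  bad_low <- if (strict_lower) any(x <= lower, na.rm = TRUE) else any(x < lower, na.rm = TRUE)
  if (bad_low || any(x > upper, na.rm = TRUE)) {
    abort_bad_arg(sprintf(
      "`%s` must be %s %s and <= %s.", name,
      if (strict_lower) ">" else ">=", format(lower), format(upper)
    ))
  }
  invisible(x)
}

check_columns <- function(data, cols, name = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort_bad_arg(sprintf(
      "`%s` is missing required column(s): %s.", name,
      paste0("`", missing, "`", collapse = ", ")
    ))
  }
  invisible(data)
}

# Monotone (non-overshooting) cubic Hermite interpolant through anchors;
# returns a function of time that also exposes the first derivative.
monotone_backbone <- function(t, v) {
  if (length(t) == 1) {
    f <- function(tq, deriv = 0) if (deriv == 0) rep(v, length(tq)) else rep(0, length(tq))
    return(f)
  }
  sf <- stats::splinefun(t, v, method = "monoH.FC")
  function(tq, deriv = 0) sf(tq, deriv = deriv)
}

# Sphere-equivalent radius (um) of a volume in pl.
radius_from_volume_pl <- function(v_pl) {
  (3 * v_pl * UM3_PER_PL / (4 * pi))^(1 / 3)
}

volume_pl_from_radius <- function(r_um) {
  4 / 3 * pi * r_um^3 / UM3_PER_PL
}

# Linear interpolation of per-quantity noise SD between SD anchors;
# constant extrapolation beyond the anchored range.
interp_sd <- function(t_anchor, sd_anchor, tq) {
  if (length(t_anchor) == 1) {
    return(rep(sd_anchor, length(tq)))
  }
  stats::approx(t_anchor, sd_anchor, xout = tq, rule = 2)$y
}
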