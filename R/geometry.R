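#' Sphere-equivalent shell geometry from lumen and vesicle volumes
#'
#' Reduces the vesicle to a thin spherical shell: the lumen radius `Rl` and
#' outer radius `Ro` are the radii of spheres with the lumen volume `Vl`
#' and total vesicle volume `Vo`, the average radius is `R = (Ro + Rl)/2`
#' and the wall thickness is `h = Ro - Rl`.
#'
#' @param data Data frame with columns `Vl` and `Vo` (pl), or `NULL` to use
#'   the `Vl`/`Vo` vectors directly.
#' @param Vl,Vo Lumen and total vesicle volumes (pl), used when `data` is
#'   `NULL`. `Vo > Vl >= 0` is required.
#' @return A tibble with columns `Rl`, `Ro`, `R`, `h` (um); when `data` is
#'   supplied its columns are kept alongside.
#' @export
#' @examples
#' shell_from_volumes(Vl = 440, Vo = 807)
shell_from_volumes <- function(data = NULL, Vl = NULL, Vo = NULL) {
  if (!is.null(data)) {
    check_columns(data, c("Vl", "Vo"), "data")
    Vl <- data$Vl
    Vo <- data$Vo
  }
  check_number(Vl, "Vl", lower = 0)
  check_number(Vo, "Vo", lower = 0)
  if (any(Vo <= Vl)) {
    abort_bad_arg("`Vo` must exceed `Vl` (the wall has positive volume).")
  }
  geom <- tibble::tibble(
    Rl = radius_from_volume_pl(Vl),
    Ro = radius_from_volume_pl(Vo)
  )
  geom$R <- (geom$Ro + geom$Rl) / 2
  geom$h <- geom$Ro - geom$Rl
  if (!is.null(data)) {
    return(dplyr::bind_cols(tibble::as_tibble(data), geom))
  }
  geom
}
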