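#' Light/dark schedule
#'
#' Describes the lighting cycle the animals are entrained to. Zeitgeber time
#' (ZT) is measured in hours since lights-on: ZT 0 is lights-on and, under the
#' default 12 h:12 h cycle, ZT 12 is lights-off. The light (rest) phase is the
#' half-open interval \[`lights_on_zt`, `lights_off_zt`) and the dark (active)
#' phase is the remainder of the period.
#'
#' @param lights_on_zt Hour of lights-on; defines ZT 0. Default 0.
#' @param lights_off_zt Hour of lights-off, strictly inside `[0, period)`.
#'   Default 12.
#' @param period Cycle length in hours. Default 24.
#'
#' @return An object of class `light_dark_schedule`.
#' @export
#' @examples
#' sched <- light_dark_schedule()
#' phase_of_zt(c(0, 11.99, 12, 23.9), sched)
light_dark_schedule <- function(lights_on_zt = 0, lights_off_zt = 12, period = 24) {
  if (!is.numeric(period) || length(period) != 1 || period <= 0) {
    abort_validation("`period` must be a single positive number of hours.")
  }
  if (!is.numeric(lights_off_zt) || length(lights_off_zt) != 1 ||
      lights_off_zt <= 0 || lights_off_zt >= period) {
    abort_validation("`lights_off_zt` must lie strictly inside (0, period).")
  }
  structure(
    list(lights_on_zt = lights_on_zt, lights_off_zt = lights_off_zt, period = period),
    class = "light_dark_schedule"
  )
}

#' Phase (light or dark) at a zeitgeber time
#'
#' @param zt Numeric vector of zeitgeber times in hours; values are wrapped
#'   modulo the schedule period.
#' @param schedule A [light_dark_schedule()].
#'
#' @return Factor with levels `"light"`, `"dark"`.
#' @export
phase_of_zt <- function(zt, schedule = light_dark_schedule()) {
  stopifnot(inherits(schedule, "light_dark_schedule"))
  h <- (zt - schedule$lights_on_zt) %% schedule$period
  factor(ifelse(h < (schedule$lights_off_zt - schedule$lights_on_zt), "light", "dark"),
         levels = c("light", "dark"))
}

# ZT (hours, wrapped to [0, 24)) of each epoch given a start ZT.
zt_of_epoch <- function(epoch_index, start_zt, period = 24) {
  (start_zt + epoch_index * epoch_seconds() / 3600) %% period
}

#' @export
print.light_dark_schedule <- function(x, ...) {
  cat(sprintf(
    "<light_dark_schedule> lights on ZT %g, off ZT %g, period %g h\n",
    x$lights_on_zt, x$lights_off_zt, x$period
  ))
  invisible(x)
}
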