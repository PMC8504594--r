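# Printed reference doses from the physical study: per-thickness mean
# simulated and glass-dosimeter-measured mean glandular doses for the Rh and
# Ag filters. Read-only comparison fixtures; nothing in the pipeline is fit
# to them except the single absolute-dose anchor cell (see absolute_dose()).

#' Reference mean-glandular-dose table
#'
#' Mean simulated and measured doses (mGy) per breast thickness and
#' additional filter, plus the overall per-filter means, as published for
#' the physical 3D-printed phantom study. Used only for comparison reports.
#'
#' @return A data.frame with columns `thickness_cm`, `filter`,
#'   `simulated_mGy`, `measured_mGy`, `measured_spread_mGy`, and an
#'   `overall` attribute holding the per-filter overall means.
#' @export
#' @examples
#' fx <- fixture_table()
#' subset(fx, thickness_cm == 4 & filter == "Rh")$simulated_mGy
fixture_table <- function() {
  tab <- data.frame(
    thickness_cm = rep(c(4, 4.5, 5), each = 2),
    filter = rep(c("Rh", "Ag"), times = 3),
    simulated_mGy = c(0.68, 0.98, 0.64, 0.88, 0.58, 0.82),
    measured_mGy = c(0.66, 0.98, 0.62, 0.85, 0.59, 0.83),
    measured_spread_mGy = c(0.02, 0.03, 0.02, 0.03, 0.02, 0.02),
    stringsAsFactors = FALSE
  )
  attr(tab, "overall") <- data.frame(
    filter = c("Rh", "Ag"),
    simulated_mGy = c(0.72, 1.00),
    measured_mGy = c(0.62, 0.89),
    measured_spread_mGy = c(0.02, 0.03),
    stringsAsFactors = FALSE
  )
  tab
}
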