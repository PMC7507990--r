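# Dot-separated parameter paths used by the sensitivity machinery.
# Supported families:
#   prices.<drug>            ae_costs.<event>        other_costs.<item>
#   utilities.<field>        intervention.ae.<event>  comparator.ae.<event>

split_path <- function(path) strsplit(path, ".", fixed = TRUE)[[1]]

#' Resolve a parameter path to its current value
#'
#' @param scenario A `cea_scenario`.
#' @param path Dot-separated path, e.g. `"prices.nivolumab"`,
#'   `"utilities.pd"` or `"comparator.ae.anemia"` (an adverse-event path
#'   addresses the risk).
#' @return The numeric value at the path.
#' @export
get_param <- function(scenario, path) {
  p <- split_path(path)
  bad <- function() fail("cannot resolve parameter path '", path, "'")
  if (length(p) == 2L && p[1] %in% c("prices", "ae_costs", "other_costs",
                                     "utilities")) {
    v <- scenario[[p[1]]][[p[2]]]
    if (is.null(v)) bad()
    return(v)
  }
  if (length(p) == 3L && p[1] %in% c("intervention", "comparator") &&
      p[2] == "ae") {
    for (ae in scenario[[p[1]]]$ae) if (identical(ae$name, p[3])) return(ae$risk)
    bad()
  }
  bad()
}

#' Set a parameter by path
#'
#' Returns a modified copy of the scenario; used to rebuild the pipeline at
#' perturbed parameter values in the one-way and probabilistic sensitivity
#' analyses.
#'
#' @inheritParams get_param
#' @param value New numeric value.
#' @return The modified scenario.
#' @export
set_param <- function(scenario, path, value) {
  p <- split_path(path)
  get_param(scenario, path)  # errors early on a bad path
  if (length(p) == 2L) {
    scenario[[p[1]]][[p[2]]] <- value
  } else {
    for (i in seq_along(scenario[[p[1]]]$ae)) {
      if (identical(scenario[[p[1]]]$ae[[i]]$name, p[3]))
        scenario[[p[1]]]$ae[[i]]$risk <- value
    }
  }
  scenario
}
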