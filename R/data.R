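# Shipped reference tables.

#' Published Lake Grevelingen incubation summary
#'
#' The per-core cumulative fluxes (mmol m-2) of dissolved As, dissolved Fe
#' and free sulfide from the long-term anoxic whole-core incubations of
#' seasonally hypoxic Lake Grevelingen sediment (three replicate cores per
#' campaign: March, May, August), as published. Shipped as plain CSV under
#' `extdata` together with the matching upper-1-cm ascorbate-extraction
#' inventory changes.
#'
#' @param which `"cumulative"` (default) or `"inventory_change"`.
#' @return A data.frame.
#' @examples
#' tab <- grevelingen_summary()
#' subset(tab, campaign == "march" & species == "dAs")
#' @export
grevelingen_summary <- function(which = c("cumulative",
                                          "inventory_change")) {
  which <- match.arg(which)
  f <- switch(which,
              cumulative = "grevelingen_cumulative_fluxes.csv",
              inventory_change = "grevelingen_inventory_change.csv")
  utils::read.csv(system.file("extdata", f, package = "benthicflux",
                              mustWork = TRUE), stringsAsFactors = FALSE)
}
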