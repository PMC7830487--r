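#' Reference quality-parameter table for germinating mung bean sprouts
#'
#' Published summary statistics (mean, sd, n = 3) of gravimetric water
#' content, extract pH and extract conductivity for 21 germination time
#' points (0-120 h in 6 h steps), together with the growth stage labels
#' and the DMRT letter groupings the source table reports. These summary
#' values anchor the synthetic generators and the summary-statistics
#' ANOVA/DMRT entry points; the underlying raw triplicates are not
#' available.
#'
#' @return Data frame with one row per germination time.
#' @export
sprout_quality_reference <- function() {
  utils::read.csv(system.file("extdata", "quality_reference.csv",
                              package = "sproutspec"),
                  stringsAsFactors = FALSE)
}

#' Reference ascorbic acid table (titration vs NIR prediction)
#'
#' Published ascorbic acid content of sprout extract (mg per 100 g of
#' beans; mean, sd, n = 3) at six germination times, determined by
#' iodometric titration and by the NIR calibration model, with the DMRT
#' letters of the source table.
#'
#' @return Data frame with one row per 24 h germination time.
#' @export
sprout_ascorbic_reference <- function() {
  utils::read.csv(system.file("extdata", "ascorbic_reference.csv",
                              package = "sproutspec"),
                  stringsAsFactors = FALSE)
}
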