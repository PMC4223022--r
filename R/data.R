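#' @include AllClasses.R
NULL

#' Bundled brain-tumor delineation study tables
#'
#' Per-observer results of a three-patient, three-observer brain-tumor GTV
#' delineation study comparing dual-modality (MRI/CT) against tri-modality
#' (MRI/CT/PET) image fusion:
#' \describe{
#'   \item{"volumes"}{GTV volumes (cm^3) per patient, scheme and observer.}
#'   \item{"adsc"}{average distance between surface and centroid (cm) per
#'     patient, scheme and observer.}
#'   \item{"intraobserver"}{per observer, patient and scheme the mean, SD
#'     (cm^3) and COV of three repeat delineations about two months apart.}
#' }
#' These tables are inputs for the statistics pipeline (volume COV, ADSC
#' mean/SD, paired two-tailed t-tests), e.g. via
#' \code{\link{variationReport}}.
#'
#' @param which one of "volumes", "adsc", "intraobserver".
#' @return a data.frame.
#' @export
#' @examples
#' v <- studyTable("volumes")
#' covReport(v$volume_cm3[v$patient == 1 & v$scheme == "dual"])$cov
studyTable <- function(which = c("volumes", "adsc", "intraobserver")) {
  which <- match.arg(which)
  f <- switch(which, volumes = "gtv_volumes.csv", adsc = "gtv_adsc.csv",
              intraobserver = "gtv_intraobserver.csv")
  utils::read.csv(system.file("extdata", f, package = "trifuse",
                              mustWork = TRUE))
}
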