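#' Published apricot chilling and heat requirements
#'
#' Mean per-cultivar requirement values for 20 apricot cultivars as
#' published for the four break-date methods (forcing test, correlation
#' model, PLS regression, male-meiosis biomarker), shipped as plain-text
#' CSVs under `inst/extdata`. Chilling requirements are in chill portions
#' (Dynamic model), heat requirements in growing degree hours;
#' `published_class` carries the published band membership of the
#' male-meiosis estimates (see [classify_cr()] and [classify_hr()]).
#' Useful as worked-example input and as reference values for
#' classification and range summaries.
#'
#' @return A list of two data frames, `cr` (chill portions, columns
#'   `cultivar`, `forcing_cp`, `correlation_cp`, `pls_cp`, `meiosis_cp`,
#'   `published_class`) and `hr` (growing degree hours, analogous columns).
#' @examples
#' pub <- published_requirements()
#' column_summary(pub$cr$forcing_cp)
#' @export
published_requirements <- function() {
  path <- function(f) system.file("extdata", f, package = "chillreq",
                                  mustWork = TRUE)
  list(cr = read.csv(path("apricot_cr_published.csv"), check.names = FALSE,
                     stringsAsFactors = FALSE),
       hr = read.csv(path("apricot_hr_published.csv"), check.names = FALSE,
                     stringsAsFactors = FALSE))
}
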