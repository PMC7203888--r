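#' Built-in reference cohorts
#'
#' The package ships the published aggregate counts of a two-cohort
#' before/after study of a comprehensive labour-management protocol at a
#' large northern-Italian obstetric unit: the path-count tables of the
#' baseline cohort (`"bcm_paths"`, N = 637, before the protocol change)
#' and the follow-up cohort (`"acm_paths"`, N = 1375, after it) on the
#' default A/V/C protocol, and the corresponding full-ward Robson
#' ten-group count tables (`"bcm_robson"`: 912 women, 285 caesareans;
#' `"acm_robson"`: 1905 women, 509 caesareans).  These are the worked
#' examples used across the documentation and the validation suite.
#'
#' @param name One of `"bcm_paths"`, `"acm_paths"`, `"bcm_robson"`,
#'   `"acm_robson"`.
#' @return A [path_count_table()] for the `*_paths` fixtures, a validated
#'   Robson count data frame for the `*_robson` ones.
#' @examples
#' load_fixture("bcm_paths")
#' @export
load_fixture <- function(name) {
  available <- c("bcm_paths", "acm_paths", "bcm_robson", "acm_robson")
  if (!is.character(name) || length(name) != 1 || !name %in% available)
    stop("unknown fixture; available: ", paste(available, collapse = ", "),
         call. = FALSE)
  file <- system.file("extdata", paste0(name, ".csv"),
                      package = "iatropath", mustWork = TRUE)
  if (endsWith(name, "_paths")) read_path_counts(file)
  else read_robson_csv(file)
}
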