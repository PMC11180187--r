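#' Rice grain-yield fixtures from a two-regime irrigation trial
#'
#' Grain-yield means (t/ha) of five rice genotypes (G1 Binadhan-10, G2
#' Binadhan-8, G3 BRRI dhan29, G4 BRRI dhan47, G5 Binadhan-17) grown in nine
#' environments in Bangladesh under two irrigation regimes: alternate
#' wetting-and-drying (AWD) and continuous flooding (CF). Each cell is the
#' mean of three replicates of a split-plot trial. These matrices anchor the
#' package's worked examples and regression tests: the AWD grand mean is 4.85
#' and the CF grand mean 4.84 t/ha (2 dp).
#'
#' @param regime `"AWD"` or `"CF"`.
#' @return A [means_matrix()] (5 genotypes x 9 environments, `n_reps = 3`,
#'   trait `"GY"`).
#' @examples
#' m <- yield_fixture("AWD")
#' margin_means(m)$grand
#' @export
yield_fixture <- function(regime = c("AWD", "CF")) {
  regime <- match.arg(regime)
  # rows E1..E9, columns G1..G5, as printed (t/ha, 2 dp)
  awd <- c(
    5.03, 4.90, 5.30, 5.43, 5.37,
    4.97, 4.73, 5.40, 5.00, 5.27,
    4.43, 3.77, 4.30, 4.23, 4.80,
    5.13, 5.03, 5.03, 5.13, 5.37,
    4.70, 4.50, 4.53, 4.43, 4.80,
    4.83, 4.50, 4.40, 4.90, 4.23,
    5.07, 4.70, 5.37, 4.87, 5.23,
    4.67, 4.57, 4.97, 4.93, 4.67,
    4.83, 4.90, 5.23, 5.13, 4.57)
  cf <- c(
    5.07, 5.13, 5.10, 5.30, 4.83,
    5.00, 5.23, 4.80, 5.40, 5.27,
    4.27, 4.47, 4.07, 4.60, 3.97,
    5.17, 4.83, 5.37, 5.33, 5.27,
    4.63, 4.33, 4.90, 4.87, 4.77,
    4.50, 3.70, 4.80, 4.30, 4.70,
    5.20, 5.07, 5.23, 4.63, 4.63,
    4.63, 5.03, 4.50, 5.37, 4.57,
    5.07, 4.80, 4.93, 5.43, 4.77)
  v <- if (regime == "AWD") awd else cf
  by_env <- matrix(v, nrow = 9, ncol = 5, byrow = TRUE,
                   dimnames = list(paste0("E", 1:9), paste0("G", 1:5)))
  means_matrix(t(by_env), n_reps = 3L, trait = "GY")
}
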