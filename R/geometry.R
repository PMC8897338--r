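#' DNA volume geometry of the transforming cell
#'
#' Bundles the volumetric quantities of the multi-hit model: the volume `V`
#' of the whole DNA molecule, the threshold volume `V_T` of mutated
#' oncogenes at which the cell counts as neoplastically transformed, and the
#' fraction `mu` of genes that are proto-oncogenes (driver genes). Volumes
#' are in arbitrary but common units; only the ratio `V_T / V` enters the
#' closed-form probabilities.
#'
#' The model requires `V_T << V`; the constructor enforces the strict
#' inequality and warns when the ratio exceeds 0.1, where the rare-hit
#' approximations start to degrade.
#'
#' @param total_volume Volume `V` of the whole DNA molecule (positive).
#' @param threshold_volume Threshold volume `V_T` of mutated oncogenes
#'   (positive, strictly less than `total_volume`).
#' @param oncogene_fraction Fraction `mu` of genes that are proto-oncogenes,
#'   in `(0, 1]`. Defaults to 0.015, the human driver-gene fraction (see
#'   [driver_gene_fraction()]).
#'
#' @return An object of class `"genome_geometry"`: a list with fields
#'   `total_volume`, `threshold_volume`, `oncogene_fraction` and the derived
#'   `ratio = threshold_volume / total_volume`.
#' @seealso [single_hit_probability()], [oncogenic_hit_probability_exact()]
#' @examples
#' geom <- genome_geometry(total_volume = 1, threshold_volume = 1e-4)
#' geom$ratio
#' @export
genome_geometry <- function(total_volume = 1,
                            threshold_volume = 1e-3,
                            oncogene_fraction = 0.015) {
  total_volume <- check_scalar(total_volume, "total_volume",
                               lower = 0, strict_lower = TRUE)
  threshold_volume <- check_scalar(threshold_volume, "threshold_volume",
                                   lower = 0, strict_lower = TRUE)
  oncogene_fraction <- check_scalar(oncogene_fraction, "oncogene_fraction",
                                    lower = 0, upper = 1, strict_lower = TRUE)
  if (threshold_volume >= total_volume) {
    stop("`threshold_volume` must be strictly less than `total_volume` ",
         "(the model assumes V_T << V)", call. = FALSE)
  }
  ratio <- threshold_volume / total_volume
  if (ratio > 0.1) {
    warning("threshold_volume / total_volume = ", signif(ratio, 3),
            " > 0.1; the model assumes V_T << V", call. = FALSE)
  }
  structure(
    list(total_volume = total_volume,
         threshold_volume = threshold_volume,
         oncogene_fraction = oncogene_fraction,
         ratio = ratio),
    class = "genome_geometry"
  )
}

#' @export
print.genome_geometry <- function(x, ...) {
  cat("Genome geometry (volumetric multi-hit model)\n")
  cat(sprintf("  DNA volume V:           %g\n", x$total_volume))
  cat(sprintf("  threshold volume V_T:   %g  (ratio V_T/V = %g)\n",
              x$threshold_volume, x$ratio))
  cat(sprintf("  oncogene fraction mu:   %g\n", x$oncogene_fraction))
  invisible(x)
}

#' Driver-gene fraction of the human genome
#'
#' The fraction of human genes identified as cancer driver genes
#' (proto-oncogenes): 299 driver genes out of roughly 20,000 genes, giving
#' mu = 299/20000 = 0.01495, conventionally quoted as 0.015. This is the
#' default conversion factor between the total mutation count `M` and the
#' oncogenic mutation count `m = mu * M`.
#'
#' @param n_driver Number of driver genes (default 299).
#' @param n_genes Total number of genes (default 20000).
#' @return The fraction `n_driver / n_genes`.
#' @examples
#' driver_gene_fraction() # 0.01495, i.e. ~0.015
#' @export
driver_gene_fraction <- function(n_driver = 299, n_genes = 20000) {
  n_driver <- check_scalar(n_driver, "n_driver", lower = 0, strict_lower = TRUE)
  n_genes <- check_scalar(n_genes, "n_genes", lower = 0, strict_lower = TRUE)
  if (n_driver > n_genes) {
    stop("`n_driver` cannot exceed `n_genes`", call. = FALSE)
  }
  n_driver / n_genes
}
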