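#' Feature density for one analysis region
#'
#' Upstream densities are counts per kilobase; genic densities are counts
#' per 10 kilobases (a scaling that brings genic values to a magnitude
#' comparable with the short upstream windows).
#'
#' @param nFeatures feature count in the region.
#' @param regionLength region length in bases (> 0).
#' @param kind \code{"upstream5kb"} or \code{"genic"}.
#' @return numeric density.
#' @export
regionDensity <- function(nFeatures, regionLength, kind) {
  if (any(regionLength <= 0)) .stopf("zero-length region")
  if (!all(kind %in% c("upstream5kb", "genic")))
    .stopf("kind must be upstream5kb or genic")
  scale <- ifelse(kind == "genic", 10000, 1000)
  nFeatures / (regionLength / scale)
}

#' Per-gene Alu density table
#'
#' @param alus host-assigned Alu \code{GRanges}.
#' @param regions region \code{GRanges} from [extractRegions()].
#' @return data.frame with \code{gene_id}, \code{region_kind},
#'   \code{metric = "alu_density"}, \code{value}; genes with no Alus get 0.
#' @export
aluDensityTable <- function(alus, regions) {
  key <- paste(mcols(regions)$gene_id, mcols(regions)$kind)
  n <- integer(length(regions))
  if (length(alus)) {
    tab <- table(paste(mcols(alus)$host_gene, mcols(alus)$region_kind))
    m <- match(key, names(tab))
    n[!is.na(m)] <- as.integer(tab[m[!is.na(m)]])
  }
  data.frame(gene_id = mcols(regions)$gene_id,
             region_kind = mcols(regions)$kind,
             metric = "alu_density",
             value = regionDensity(n, width(regions), mcols(regions)$kind),
             stringsAsFactors = FALSE)
}

#' Per-gene HSF site density table
#'
#' @param classified classified-hit data.frame.
#' @param regions region \code{GRanges}.
#' @param metric one of \code{hsf_density_total}, \code{hsf_density_alu},
#'   \code{hsf_density_nonalu}.
#' @return data.frame as [aluDensityTable()].
#' @export
hsfDensityTable <- function(classified,
                            regions,
                            metric = c("hsf_density_total",
                                       "hsf_density_alu",
                                       "hsf_density_nonalu")) {
  metric <- match.arg(metric)
  sel <- switch(metric,
                hsf_density_total = rep(TRUE, nrow(classified)),
                hsf_density_alu = classified$in_alu,
                hsf_density_nonalu = !classified$in_alu)
  cl <- classified[sel, , drop = FALSE]
  key <- paste(mcols(regions)$gene_id, mcols(regions)$kind)
  n <- integer(length(regions))
  if (nrow(cl)) {
    tab <- table(paste(cl$gene_id, cl$region_kind))
    m <- match(key, names(tab))
    n[!is.na(m)] <- as.integer(tab[m[!is.na(m)]])
  }
  data.frame(gene_id = mcols(regions)$gene_id,
             region_kind = mcols(regions)$kind,
             metric = metric,
             value = regionDensity(n, width(regions), mcols(regions)$kind),
             stringsAsFactors = FALSE)
}

#' Compare per-gene densities between two groups (Welch t-test)
#'
#' Two-sample two-tailed t-test without the equal-variance assumption
#' (Welch), the gene being the sampling unit.
#'
#' @param valuesA,valuesB numeric vectors of per-gene densities.
#' @param labelA,labelB group labels for the report row.
#' @return data.frame row with group labels, sizes, means, \code{t_statistic}
#'   and two-tailed \code{p_value}.
#' @export
compareGroups <- function(valuesA, valuesB,
                          labelA = "A", labelB = "B") {
  if (length(valuesA) < 2L || length(valuesB) < 2L)
    .stopf("each group needs at least 2 values")
  if (stats::var(valuesA) == 0 && stats::var(valuesB) == 0)
    .stopf("zero variance in both groups")
  tt <- t.test(valuesA, valuesB, var.equal = FALSE,
               alternative = "two.sided")
  data.frame(group_a = labelA, group_b = labelB,
             n_a = length(valuesA), n_b = length(valuesB),
             mean_a = mean(valuesA), mean_b = mean(valuesB),
             t_statistic = unname(tt$statistic),
             p_value = tt$p.value, stringsAsFactors = FALSE)
}
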