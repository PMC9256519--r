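#' Region labels: 90 non-cerebellar AAL regions
#'
#' The standard automated-anatomical-labelling parcellation restricted to the
#' 90 cerebral regions (cerebellum and vermis excluded), in the conventional
#' left/right interleaved order. Used as the default atlas for 90-region
#' inputs; inputs with any other region count supply their own labels.
#'
#' @return character vector of 90 region names (suffix `_L` / `_R`)
#' @export
#' @examples
#' head(aal90_labels())
aal90_labels <- function() {
  base <- c(
    "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
    "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
    "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
    "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
    "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
    "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
    "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
    "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
    "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
    "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
    "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf")
  as.vector(rbind(paste0(base, "_L"), paste0(base, "_R")))
}

#' Default labels for an arbitrary region count
#'
#' @param n number of regions
#' @return `aal90_labels()` when `n == 90`, otherwise `R001 ... Rnnn`
#' @export
default_region_labels <- function(n) {
  if (n == 90) aal90_labels() else sprintf("R%03d", seq_len(n))
}
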