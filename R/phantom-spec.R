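#' Functional and cytoarchitectonic class labels used by default
#'
#' Seven Yeo-style functional classes (VIS and SM are unimodal; DA, VA, LIM,
#' FP and DMN transmodal) and seven von Economo-style cytoarchitectonic
#' classes.
#'
#' @name node_classes
NULL

functional_classes <- c("VIS", "SM", "DA", "VA", "LIM", "FP", "DMN")
unimodal_classes <- c("VIS", "SM")
transmodal_classes <- setdiff(functional_classes, unimodal_classes)
cyto_classes <- c("PM", "INS", "LIM", "PS", "PSS", "ASC1", "ASC2")

#' Specification of a synthetic connectome phantom
#'
#' Describes a cohort of subjects whose NOS-weighted connectomes have planted
#' modular structure and whose scalar (R1-like) edge weights carry a planted
#' node-class effect. Used both to generate connectivity matrices directly
#' (`generate_cohort_matrices()`) and, for a small number of regions, full
#' phantom geometry (`generate_phantom_geometry()`).
#'
#' Edge model: a population template edge exists between a region pair with
#' probability `edge_prob_within` (same planted module) or
#' `edge_prob_between`; each subject retains a template edge with probability
#' `subject_keep`, so the 50%-prevalence consensus rule has both kept and
#' rejected edges to act on. On present edges the streamline count is Poisson
#' with mean `lambda_within` or `lambda_between`, truncated to be at least 1,
#' with a mean-preserving log-normal per-subject rate fluctuation of relative
#' spread `subject_noise_sd`. The scalar weight of an edge is `scalar_base`
#' plus the mean of its two endpoint functional-class offsets
#' (`scalar_class_effect`) plus Gaussian noise of SD `scalar_noise_sd`,
#' clipped to the physiological envelope (0, 3) 1/s.
#'
#' @param n_regions number of nodes (geometry mode supports at most 8).
#' @param n_subjects cohort size (default 35).
#' @param n_modules number of equal-sized planted modules (used when
#'   `planted_partition` is not given).
#' @param planted_partition integer module label per node, contiguous from 1.
#' @param lambda_within,lambda_between mean streamline counts for
#'   within-/between-module pairs; must satisfy
#'   `lambda_within > lambda_between >= 0`.
#' @param edge_prob_within,edge_prob_between template edge probabilities.
#' @param subject_keep probability a subject retains a template edge.
#' @param scalar_base baseline scalar value, 1/s (default 1.1, a typical
#'   white-matter R1 at 3T).
#' @param scalar_class_effect named numeric vector of additive offsets (1/s)
#'   per functional class; default +0.05 on the transmodal classes.
#' @param scalar_noise_sd edge-level scalar noise SD, 1/s.
#' @param subject_noise_sd relative per-subject fluctuation of the Poisson
#'   rate.
#' @param class_map optional data frame with columns `node`, `functional`,
#'   `cyto`; by default classes are assigned round-robin so they are
#'   orthogonal to the planted modules.
#' @param grid_shape,voxel_size geometry mode: volume dimensions (voxels)
#'   and isotropic voxel size (mm).
#' @param seed default seed used when the generator is called without one.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_regions = 60, n_subjects = 35, n_modules = 4,
                         planted_partition = NULL,
                         lambda_within = 20, lambda_between = 2,
                         edge_prob_within = 0.9, edge_prob_between = 0.1,
                         subject_keep = 0.8,
                         scalar_base = 1.1,
                         scalar_class_effect = default_class_effect(),
                         scalar_noise_sd = 0.05,
                         subject_noise_sd = 0.1,
                         class_map = NULL,
                         grid_shape = c(80, 80, 80), voxel_size = 2,
                         seed = 1L) {
  if (n_regions < 2) stop_param("need at least 2 regions")
  if (!(lambda_within > lambda_between) || lambda_between < 0)
    stop_param("need lambda_within > lambda_between >= 0")
  for (p in c(edge_prob_within, edge_prob_between, subject_keep))
    if (p < 0 || p > 1) stop_param("probabilities must lie in [0, 1]")
  if (scalar_base <= 0 || scalar_base >= 3)
    stop_param("scalar_base must lie in (0, 3) 1/s")
  if (scalar_noise_sd < 0 || subject_noise_sd < 0)
    stop_param("noise SDs must be non-negative")
  if (is.null(planted_partition)) {
    if (n_modules < 1 || n_modules > n_regions)
      stop_param("n_modules must lie in [1, n_regions]")
    planted_partition <- sort(rep_len(seq_len(n_modules), n_regions))
  }
  planted_partition <- as.integer(planted_partition)
  if (length(planted_partition) != n_regions)
    stop_param("planted_partition must label every node")
  if (!identical(sort(unique(planted_partition)),
                 seq_len(max(planted_partition))))
    stop_param("planted_partition labels must be contiguous from 1")
  if (is.null(class_map)) class_map <- default_class_map(n_regions)
  if (!all(c("node", "functional", "cyto") %in% names(class_map)))
    stop_param("class_map needs columns node, functional, cyto")
  if (nrow(class_map) != n_regions || anyNA(class_map))
    stop_param("every node must be classed in both schemes")
  miss <- setdiff(unique(class_map$functional), names(scalar_class_effect))
  if (length(miss))
    stop_param("scalar_class_effect missing classes: ",
               paste(miss, collapse = ", "))
  structure(list(n_regions = as.integer(n_regions),
                 n_subjects = as.integer(n_subjects),
                 planted_partition = planted_partition,
                 lambda_within = lambda_within,
                 lambda_between = lambda_between,
                 edge_prob_within = edge_prob_within,
                 edge_prob_between = edge_prob_between,
                 subject_keep = subject_keep,
                 scalar_base = scalar_base,
                 scalar_class_effect = scalar_class_effect,
                 scalar_noise_sd = scalar_noise_sd,
                 subject_noise_sd = subject_noise_sd,
                 class_map = class_map,
                 grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default planted class effect: transmodal classes run 0.05 1/s higher
#' @return named numeric vector over the seven functional classes.
#' @export
default_class_effect <- function() {
  eff <- stats::setNames(rep(0, length(functional_classes)),
                         functional_classes)
  eff[transmodal_classes] <- 0.05
  eff
}

# Round-robin class assignment: functional cycles with period 7, the
# cytoarchitectonic scheme in blocks of 7, so both are (near) orthogonal to
# each other and to contiguous planted modules.
default_class_map <- function(n) {
  data.frame(node = paste0("n", seq_len(n)),
             functional = rep_len(functional_classes, n),
             cyto = cyto_classes[((seq_len(n) - 1) %/% 7) %% 7 + 1],
             stringsAsFactors = FALSE)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d regions, %d subjects, %d planted modules\n",
              x$n_regions, x$n_subjects, max(x$planted_partition)))
  cat(sprintf("  NOS: lambda %g/%g, edge prob %g/%g (within/between), keep %g\n",
              x$lambda_within, x$lambda_between,
              x$edge_prob_within, x$edge_prob_between, x$subject_keep))
  cat(sprintf("  scalar: base %g 1/s, noise %g, subject spread %g\n",
              x$scalar_base, x$scalar_noise_sd, x$subject_noise_sd))
  invisible(x)
}
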