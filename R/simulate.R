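#' Simulation configuration for a synthetic stimulation-response cohort
#'
#' Builds the configuration object consumed by [simulate_cohort()]. The
#' defaults emulate the design of a large healthy-donor immune profiling
#' cohort: 86 donors, each profiled under 15 stimuli plus an unstimulated
#' reference (16 conditions), 9 gated cell types, and 15 intracellular
#' phospho-protein readouts per cell.
#'
#' Donor-to-donor coordination is generated by a latent-factor construction:
#' each donor draws one standard-normal latent propensity per signaling
#' protein, and every responsive (protein, cell type, condition) feature of
#' that protein loads on the same latent. Features sharing a protein
#' therefore co-vary across donors, which is exactly the module structure
#' the downstream correlation-network stage is meant to recover.
#'
#' Sex enters through two independent knobs:
#' * `loading_by_sex` scales the latent-factor loading per sex, changing the
#'   *strength of coordination* (within-module correlation) without moving
#'   means;
#' * `mean_shift_by_sex` adds a per-protein shift to the responsive features
#'   of one sex, changing *mean response* without changing coordination.
#'
#' @param n_donors number of donors.
#' @param n_cell_types number of gated cell types (names auto-generated from
#'   a canonical panel).
#' @param n_proteins number of phospho-protein readouts.
#' @param n_conditions total conditions including the unstimulated reference.
#' @param cells_per_sample cells per (donor, condition) sample.
#' @param response_map data.frame with columns `protein`, `cell_type`,
#'   `condition`, `effect` listing responsive features and their mean effect
#'   sizes on the arcsinh scale. `NULL` uses a default map planting one
#'   module per responsive protein (8 proteins x 4 cell types x 3 stimuli).
#' @param loading_by_sex named numeric vector (`female`, `male`) scaling the
#'   donor latent-factor loading per sex.
#' @param mean_shift_by_sex named list with elements `female` and `male`,
#'   each a named numeric vector over proteins giving additive shifts
#'   applied to that sex's responsive features of the protein.
#' @param cell_noise_sd spread of single-cell transformed values around the
#'   sample target median.
#' @param feature_noise_sd donor-level idiosyncratic noise added to each
#'   responsive feature's target median (controls within-module correlation:
#'   with loading L, planted pairwise R is roughly L^2 / (L^2 + sd^2)).
#' @param effect_size default mean effect used by the default response map.
#' @param cofactor arcsinh cofactor used when mapping transformed targets
#'   back to raw intensities (`raw = cofactor * sinh(transformed)`).
#' @param base_range range of per-(cell type, protein) baseline medians on
#'   the transformed scale.
#' @param dirichlet_conc concentration of the Dirichlet draw of per-sample
#'   cell-type proportions around the base proportions.
#' @param sex_prop proportion of female donors (the cohort is split
#'   deterministically as close to this as possible, then shuffled).
#'
#' @return an object of class `stimmod_config` (a validated list).
#' @export
sim_config <- function(n_donors = 86,
                       n_cell_types = 9,
                       n_proteins = 15,
                       n_conditions = 16,
                       cells_per_sample = 1000,
                       response_map = NULL,
                       loading_by_sex = c(female = 1, male = 1),
                       mean_shift_by_sex = list(female = numeric(0), male = numeric(0)),
                       cell_noise_sd = 0.6,
                       feature_noise_sd = 0.65,
                       effect_size = 0.8,
                       cofactor = 5,
                       base_range = c(0.5, 2),
                       dirichlet_conc = 300,
                       sex_prop = 0.5) {
  for (nm in c("n_donors", "n_cell_types", "n_proteins", "n_conditions",
               "cells_per_sample")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1)
      stop("'", nm, "' must be a positive count", call. = FALSE)
  }
  if (n_conditions < 2)
    stop("'n_conditions' must include the unstimulated reference and at least one stimulus",
         call. = FALSE)
  if (!all(c("female", "male") %in% names(loading_by_sex)))
    stop("'loading_by_sex' must name both 'female' and 'male'", call. = FALSE)
  loading_by_sex <- as.list(loading_by_sex)[c("female", "male")]
  for (sx in c("female", "male")) {
    l <- loading_by_sex[[sx]]
    if (!is.numeric(l) || !all(is.finite(l)) ||
        !(length(l) == 1L || !is.null(names(l))))
      stop("'loading_by_sex$", sx,
           "' must be a finite scalar or a named vector over proteins",
           call. = FALSE)
  }
  if (!is.list(mean_shift_by_sex) ||
      !all(c("female", "male") %in% names(mean_shift_by_sex)))
    stop("'mean_shift_by_sex' must be a list with 'female' and 'male'", call. = FALSE)
  if (cell_noise_sd < 0 || feature_noise_sd < 0)
    stop("noise standard deviations must be non-negative", call. = FALSE)
  if (cofactor <= 0) stop("'cofactor' must be positive", call. = FALSE)

  proteins <- default_proteins(n_proteins)
  cell_types <- default_cell_types(n_cell_types)
  conditions <- c("unstim", sprintf("stim%02d", seq_len(n_conditions - 1L)))

  if (is.null(response_map)) {
    response_map <- default_response_map(proteins, cell_types, conditions,
                                         effect = effect_size)
  } else {
    response_map <- as.data.frame(response_map)
    need <- c("protein", "cell_type", "condition", "effect")
    miss <- setdiff(need, names(response_map))
    if (length(miss))
      stop("response_map is missing columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (!all(is.finite(response_map$effect)))
      stop("all response_map effect sizes must be finite", call. = FALSE)
    if (any(response_map$condition == "unstim"))
      stop("the unstimulated reference cannot appear in response_map", call. = FALSE)
    bad <- !(response_map$protein %in% proteins) |
      !(response_map$cell_type %in% cell_types) |
      !(response_map$condition %in% conditions)
    if (any(bad))
      stop("response_map refers to unknown protein/cell_type/condition labels",
           call. = FALSE)
  }

  for (sx in c("female", "male")) {
    sh <- mean_shift_by_sex[[sx]]
    if (length(sh) && (!is.numeric(sh) || is.null(names(sh)) ||
                       !all(names(sh) %in% proteins)))
      stop("mean_shift_by_sex$", sx, " must be a named numeric vector over proteins",
           call. = FALSE)
  }

  cfg <- list(
    n_donors = as.integer(n_donors),
    proteins = proteins,
    cell_types = cell_types,
    conditions = conditions,
    unstim = "unstim",
    cells_per_sample = as.integer(cells_per_sample),
    response_map = response_map,
    loading_by_sex = expand_loadings(loading_by_sex, proteins),
    mean_shift_by_sex = mean_shift_by_sex[c("female", "male")],
    cell_noise_sd = cell_noise_sd,
    feature_noise_sd = feature_noise_sd,
    cofactor = cofactor,
    base_range = base_range,
    dirichlet_conc = dirichlet_conc,
    sex_prop = sex_prop
  )
  class(cfg) <- "stimmod_config"
  cfg
}

default_proteins <- function(n) {
  panel <- c("pSTAT1", "pSTAT3", "pSTAT4", "pSTAT5", "pSTAT6", "pERK12",
             "pP38", "pCREB", "pMAPKAPK2", "pTBK1", "pNFkB", "pS6",
             "pPLCg2", "pAKT", "IkB")
  if (n <= length(panel)) panel[seq_len(n)] else
    c(panel, sprintf("protein%02d", seq_len(n - length(panel))))
}

default_cell_types <- function(n) {
  panel <- c("CD4T", "CD8T", "Bcells", "NKcells", "Monocytes",
             "Neutrophils", "DCs", "gdT", "Basophils")
  if (n <= length(panel)) panel[seq_len(n)] else
    c(panel, sprintf("celltype%02d", seq_len(n - length(panel))))
}

#' @keywords internal
default_response_map <- function(proteins, cell_types, conditions,
                                 n_modules = 8, cts_per_module = 4,
                                 conds_per_module = 3, effect = 0.8) {
  n_modules <- min(n_modules, length(proteins))
  stims <- setdiff(conditions, "unstim")
  cts_per_module <- min(cts_per_module, length(cell_types))
  conds_per_module <- min(conds_per_module, length(stims))
  out <- vector("list", n_modules)
  for (i in seq_len(n_modules)) {
    ct_idx <- ((i - 1L) + seq_len(cts_per_module) - 1L) %% length(cell_types) + 1L
    cd_idx <- (2L * (i - 1L) + seq_len(conds_per_module) - 1L) %% length(stims) + 1L
    out[[i]] <- expand.grid(protein = proteins[i],
                            cell_type = cell_types[ct_idx],
                            condition = stims[cd_idx],
                            stringsAsFactors = FALSE)
  }
  rm <- do.call(rbind, out)
  rm$effect <- effect
  rm
}

# sex x protein matrix of latent-factor loadings; each sex's entry may be a
# scalar (applied to every protein) or a named vector over a protein subset
expand_loadings <- function(loading_by_sex, proteins) {
  L <- matrix(1, nrow = 2, ncol = length(proteins),
              dimnames = list(c("female", "male"), proteins))
  for (sx in c("female", "male")) {
    l <- loading_by_sex[[sx]]
    if (length(l) == 1L && is.null(names(l))) {
      L[sx, ] <- l
    } else {
      bad <- setdiff(names(l), proteins)
      if (length(bad))
        stop("loading_by_sex$", sx, " names unknown protein(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      L[sx, names(l)] <- l
    }
  }
  L
}

#' Sample one donor's latent signaling propensities
#'
#' One standard-normal draw per protein. The sex-specific factor loading is
#' applied later, when the latent is injected into responsive feature means,
#' so the latent itself is sex-free.
#'
#' @param config a [sim_config()] object.
#' @param sex `"female"` or `"male"` (validated against the configured labels).
#' @return named numeric vector, one entry per protein.
#' @export
sample_donor_latents <- function(config, sex) {
  stopifnot(inherits(config, "stimmod_config"))
  if (!sex %in% rownames(config$loading_by_sex))
    stop("unknown sex label: ", sex, call. = FALSE)
  stats::setNames(stats::rnorm(length(config$proteins)), config$proteins)
}

#' Ground-truth module assignment implied by a simulation config
#'
#' Every responsive (protein, cell type, condition) feature is labelled with
#' its protein's module; all other features are `"unassigned"`. Used as the
#' oracle for planted-module recovery.
#'
#' @param config a [sim_config()] object.
#' @return named character vector over all `condition x cell_type x protein`
#'   feature ids (see [feature_id()]), values are protein names or
#'   `"unassigned"`.
#' @export
truth_modules <- function(config) {
  stopifnot(inherits(config, "stimmod_config"))
  grid <- expand.grid(protein = config$proteins,
                      cell_type = config$cell_types,
                      condition = config$conditions,
                      stringsAsFactors = FALSE)
  ids <- feature_id(grid$protein, grid$cell_type, grid$condition)
  out <- stats::setNames(rep("unassigned", nrow(grid)), ids)
  rm <- config$response_map
  if (nrow(rm))
    out[feature_id(rm$protein, rm$cell_type, rm$condition)] <- rm$protein
  out
}

#' Canonical feature identifier
#'
#' @param protein,cell_type,condition character vectors (recycled).
#' @return character vector `"protein|cell_type|condition"`.
#' @export
feature_id <- function(protein, cell_type, condition) {
  paste(protein, cell_type, condition, sep = "|")
}

#' Generate a synthetic stimulation-response cohort
#'
#' Produces per-(donor, condition) cell event tables with planted
#' protein-level module structure and (optionally) sex effects, together
#' with donor metadata and the generating ground truth.
#'
#' The generative model, all on the arcsinh-transformed scale:
#' each (cell type, protein) pair has a fixed baseline median; a responsive
#' feature's target median under stimulation is
#' `baseline + effect + loading(sex) * z[protein] + shift(sex, protein) + eps`,
#' where `z` is the donor's latent propensity vector (drawn once and reused
#' across all of that donor's samples) and `eps` is per-(donor, feature)
#' noise. Single-cell values are Normal around the sample target, and raw
#' intensities are `cofactor * sinh(transformed)` so the downstream arcsinh
#' transform inverts the construction exactly.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; the full cohort is reproducible given the seed.
#' @return an object of class `stimmod_cohort`: a list with
#'   `events` (one `data.table` with columns `donor`, `condition`,
#'   `cell_type`, and one raw-intensity column per protein),
#'   `metadata` (data.frame: `donor_id`, `sex`, `age`),
#'   `truth` (list: `module_of_feature`, `donor_latents`,
#'   `sex_effect_features`, `target_medians`), and `config`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "stimmod_config"))
  set.seed(as.integer(seed))

  nD <- config$n_donors
  proteins <- config$proteins
  cts <- config$cell_types
  conds <- config$conditions
  nP <- length(proteins); nC <- length(cts); nK <- length(conds)

  donors <- sprintf("donor%03d", seq_len(nD))
  n_f <- round(config$sex_prop * nD)
  sex <- sample(c(rep("female", n_f), rep("male", nD - n_f)))
  age <- round(stats::runif(nD, 18, 70))
  metadata <- data.frame(donor_id = donors, sex = sex, age = age,
                         stringsAsFactors = FALSE)

  # fixed baselines per (cell type, protein), transformed scale
  base <- matrix(stats::runif(nC * nP, config$base_range[1], config$base_range[2]),
                 nrow = nC, dimnames = list(cts, proteins))

  latents <- t(vapply(seq_len(nD),
                      function(i) sample_donor_latents(config, sex[i]),
                      numeric(nP)))
  dimnames(latents) <- list(donors, proteins)

  rm <- config$response_map
  rid <- feature_id(rm$protein, rm$cell_type, rm$condition)
  # donor x responsive-feature idiosyncratic noise
  eps <- matrix(stats::rnorm(nD * nrow(rm), 0, config$feature_noise_sd),
                nrow = nD, dimnames = list(donors, rid))

  shift_for <- function(sx) {
    sh <- config$mean_shift_by_sex[[sx]]
    out <- stats::setNames(rep(0, nP), proteins)
    if (length(sh)) out[names(sh)] <- sh
    out
  }
  shifts <- rbind(female = shift_for("female"), male = shift_for("male"))

  # target medians: array donors x features (full grid), transformed scale
  grid <- expand.grid(protein = proteins, cell_type = cts, condition = conds,
                      stringsAsFactors = FALSE)
  gid <- feature_id(grid$protein, grid$cell_type, grid$condition)
  base_vec <- base[cbind(grid$cell_type, grid$protein)]
  targets <- matrix(rep(base_vec, each = nD), nrow = nD,
                    dimnames = list(donors, gid))
  if (nrow(rm)) {
    for (j in seq_len(nrow(rm))) {
      id <- rid[j]
      load_vec <- config$loading_by_sex[cbind(sex, rm$protein[j])]
      targets[, id] <- targets[, id] + rm$effect[j] +
        load_vec * latents[, rm$protein[j]] +
        shifts[cbind(sex, rm$protein[j])] +
        eps[, id]
    }
  }

  # cell-type proportions per sample: Dirichlet around base proportions
  base_prop <- base_cell_type_proportions(nC)
  names(base_prop) <- cts

  ncell <- config$cells_per_sample
  n_samples <- nD * nK
  # draw cell-type counts for every sample at once
  alpha <- base_prop * config$dirichlet_conc
  gam <- matrix(stats::rgamma(n_samples * nC, shape = rep(alpha, each = n_samples)),
                nrow = n_samples)
  props <- gam / rowSums(gam)
  counts <- t(apply(props, 1L, function(p) {
    cnt <- floor(p * ncell)
    rem <- ncell - sum(cnt)
    if (rem > 0) {
      extra <- order(p * ncell - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1L
    }
    cnt
  }))

  samp_grid <- expand.grid(donor = donors, condition = conds,
                           stringsAsFactors = FALSE)
  ct_col <- rep(rep(cts, n_samples), times = as.vector(t(counts)))
  donor_col <- rep(samp_grid$donor, each = ncell)
  cond_col <- rep(samp_grid$condition, each = ncell)

  n_rows <- length(donor_col)
  prot_mat <- matrix(0, nrow = n_rows, ncol = nP,
                     dimnames = list(NULL, proteins))
  # targets is donors x features with features in expand.grid(protein,
  # cell_type, condition) order: column = p + (ct-1)*nP + (cond-1)*nP*nC
  row_donor <- match(donor_col, donors)
  ct_i <- match(ct_col, cts)
  cond_i <- match(cond_col, conds)
  col_base <- (ct_i - 1L) * nP + (cond_i - 1L) * nP * nC
  for (pi in seq_len(nP)) {
    mu <- targets[cbind(row_donor, pi + col_base)]
    tv <- stats::rnorm(n_rows, mean = mu, sd = config$cell_noise_sd)
    prot_mat[, pi] <- config$cofactor * sinh(tv)
  }

  events <- data.table::data.table(donor = donor_col, condition = cond_col,
                                   cell_type = ct_col)
  for (p in proteins) data.table::set(events, j = p, value = prot_mat[, p])

  sex_feats <- list(
    male_higher = unique(unlist(lapply(proteins[shifts["male", ] > shifts["female", ]],
                                       function(p) rid[rm$protein == p]))),
    female_higher = unique(unlist(lapply(proteins[shifts["female", ] > shifts["male", ]],
                                         function(p) rid[rm$protein == p])))
  )

  structure(list(
    events = events,
    metadata = metadata,
    truth = list(module_of_feature = truth_modules(config),
                 donor_latents = latents,
                 sex_effect_features = sex_feats,
                 target_medians = targets,
                 baselines = base),
    config = config
  ), class = "stimmod_cohort")
}

base_cell_type_proportions <- function(n) {
  p <- c(0.28, 0.20, 0.13, 0.12, 0.09, 0.08, 0.04, 0.03, 0.03)
  if (n <= length(p)) {
    out <- p[seq_len(n)]
  } else {
    out <- c(p, rep(0.02, n - length(p)))
  }
  out / sum(out)
}

#' @export
print.stimmod_cohort <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic stimulation-response cohort\n")
  cat(sprintf("  %d donors (%d female / %d male), %d conditions, %d cell types, %d proteins\n",
              cfg$n_donors, sum(x$metadata$sex == "female"),
              sum(x$metadata$sex == "male"), length(cfg$conditions),
              length(cfg$cell_types), length(cfg$proteins)))
  cat(sprintf("  %d cells per sample; %d planted responsive features across %d proteins\n",
              cfg$cells_per_sample, nrow(cfg$response_map),
              length(unique(cfg$response_map$protein))))
  invisible(x)
}
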