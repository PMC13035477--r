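#' Bundled entity expression profiles
#'
#' Returns the default chemokine program of a lymph-node state:
#'
#' * `rLN` (reactive lymph node): homeostatic chemokines are confined to
#'   stroma — FDCs express CXCL13, T-zone FRCs express CCL19/CCL21/CXCL12,
#'   endothelium contributes CXCL12 (BEC) and CCL21 (LEC) — while lymphocytes
#'   carry the matching receptors (B/T_FH: CXCR5, CXCR4; T cells: CCR7,
#'   CXCR4). Inflammatory ligands are near absent.
#' * `DLBCL` (diffuse large B cell lymphoma): homeostatic ligand means are
#'   reduced to 20% of the rLN levels, remodeled FRCs (rFRC) express the
#'   interferon-inducible ligands CXCL9/10/11 at high level, cytotoxic T
#'   cells up-regulate CXCR3, and a 30% subset of them ectopically expresses
#'   CXCL13. Overdispersion is higher, reflecting the patchy inflammatory
#'   state.
#' * `FL` (follicular lymphoma): intermediate — homeostatic at 60% of rLN,
#'   inflammatory at 40% of DLBCL, with a small rFRC fraction.
#'
#' Every profile adds a low-level constitutive program for common chemokine
#' pairs (CCL2-5/17/20/22, CXCL16 and their receptors) across all cell types,
#' so that ordinary cell pairs carry enough positive ligand-receptor scores to
#' survive the minimum-pair filter, as in real tissue.
#'
#' @param entity one of `"rLN"`, `"FL"`, `"DLBCL"`.
#' @return A list of class `entity_profile` with elements `entity`,
#'   `proportions` (named, sums to 1), `programs` (data.frame `cell_type`,
#'   `gene`, `mean`, `fraction`), `dispersion` (negative-binomial size),
#'   `background_genes`, `background_mean`.
#' @export
entity_profile <- function(entity = c("rLN", "FL", "DLBCL")) {
  entity <- match.arg(entity)
  prog <- function(cell_type, gene, mean, fraction = 1)
    data.frame(cell_type = cell_type, gene = gene, mean = mean,
               fraction = fraction, stringsAsFactors = FALSE)

  ## homeostatic ligand program at rLN level; scaled per entity below
  hom_ligands <- rbind(
    prog("FDC", "CXCL13", 25),
    prog("FRC", "CCL19", 18), prog("FRC", "CCL21", 22),
    prog("FRC", "CXCL12", 10),
    prog("BEC", "CXCL12", 8),
    prog("LEC", "CCL21", 6))

  receptors_rln <- rbind(
    prog("B", "CXCR5", 12), prog("B", "CXCR4", 8),
    prog("T_FH", "CXCR5", 10), prog("T_FH", "CXCR4", 6),
    prog("T_FH", "CCR7", 3),
    prog("T_H", "CCR7", 12), prog("T_H", "CXCR4", 6),
    prog("T_reg", "CCR7", 10), prog("T_reg", "CXCR4", 5),
    prog("T_tox", "CCR7", 8), prog("T_tox", "CXCR4", 6),
    prog("T_tox", "CXCR3", 0.5),
    prog("Macro", "CXCR4", 4))

  scale_means <- function(df, f) { df$mean <- df$mean * f; df }

  if (entity == "rLN") {
    proportions <- c(B = 0.40, T_H = 0.15, T_FH = 0.08, T_tox = 0.12,
                     T_reg = 0.05, FDC = 0.04, FRC = 0.06, BEC = 0.03,
                     LEC = 0.02, Macro = 0.05)
    programs <- rbind(hom_ligands, receptors_rln,
                      prog("FRC", "CXCL9", 0.3), prog("FRC", "CXCL10", 0.3))
    dispersion <- 2.0
  } else if (entity == "FL") {
    proportions <- c(B = 0.50, T_H = 0.10, T_FH = 0.10, T_tox = 0.10,
                     T_reg = 0.05, FDC = 0.05, FRC = 0.04, rFRC = 0.01,
                     BEC = 0.03, LEC = 0.02)
    programs <- rbind(
      scale_means(hom_ligands, 0.6),
      receptors_rln[receptors_rln$gene != "CXCR3", ],
      prog("T_tox", "CXCR3", 5),
      ## inflammatory at 40% of the DLBCL rFRC program
      prog("rFRC", "CXCL9", 8), prog("rFRC", "CXCL10", 7.2),
      prog("rFRC", "CXCL11", 4.8), prog("rFRC", "CCL19", 2))
    dispersion <- 1.5
  } else {
    proportions <- c(B = 0.55, T_H = 0.08, T_FH = 0.02, T_tox = 0.15,
                     T_reg = 0.04, FDC = 0.01, FRC = 0.03, rFRC = 0.05,
                     BEC = 0.03, LEC = 0.02, Macro = 0.02)
    receptors <- receptors_rln[!(receptors_rln$gene == "CXCR3" |
                                   (receptors_rln$cell_type == "T_H" &
                                      receptors_rln$gene == "CCR7")), ]
    programs <- rbind(
      scale_means(hom_ligands, 0.2),
      receptors,
      prog("T_H", "CCR7", 6),
      prog("T_tox", "CXCR3", 12),
      prog("T_tox", "CXCL13", 8, fraction = 0.3),   # ectopic CXCL13 subset
      prog("rFRC", "CXCL9", 20), prog("rFRC", "CXCL10", 18),
      prog("rFRC", "CXCL11", 12), prog("rFRC", "CCL19", 2),
      prog("rFRC", "CXCL12", 2),
      prog("Macro", "CXCL9", 4), prog("Macro", "CXCL10", 4))
    dispersion <- 0.8
  }

  ## constitutive chemokine background shared by all cell types
  base_genes <- c("CCL2", "CCL3", "CCL4", "CCL5", "CCL17", "CCL20", "CCL22",
                  "CXCL16", "CCR2", "CCR5", "CCR4", "CCR6", "CXCR6")
  baseline <- do.call(rbind, lapply(names(proportions), function(ct)
    prog(ct, base_genes, 2)))
  programs <- rbind(programs, baseline)

  ## registry genes with no program in this entity are still part of the
  ## measured gene universe (all-zero rows)
  reg <- lr_registry()
  zero_genes <- setdiff(c(reg$ligand, reg$receptor), programs$gene)

  stopifnot(abs(sum(proportions) - 1) < 1e-9)
  structure(list(entity = entity, proportions = proportions,
                 programs = programs, zero_genes = zero_genes,
                 dispersion = dispersion,
                 background_genes = 30L, background_mean = 0.4),
            class = "entity_profile")
}

#' Stromal or hematopoietic compartment of a cell type
#' @param cell_type character vector of cell type labels.
#' @return Character vector, `"stromal"` or `"hematopoietic"`.
#' @export
compartment_of <- function(cell_type) {
  stromal <- c("FDC", "FRC", "rFRC", "BEC", "rBEC", "LEC")
  ifelse(cell_type %in% stromal, "stromal", "hematopoietic")
}

#' Programmed chemokine ligand totals of a profile
#'
#' Sums programmed ligand means, weighted by cell type proportion and
#' expressing fraction, separately for homeostatic and inflammatory ligands.
#' Used to check the planted entity gradient (homeostatic falling, and
#' inflammatory rising, from reactive tissue to DLBCL).
#'
#' @param profile an [entity_profile()].
#' @param registry an [lr_registry()] supplying ligand classes.
#' @return Named numeric vector with elements `homeostatic` and
#'   `inflammatory`.
#' @export
program_ligand_totals <- function(profile, registry = lr_registry()) {
  p <- profile$programs
  p$weight <- profile$proportions[p$cell_type] * p$fraction * p$mean
  cls <- setNames(registry$class, registry$ligand)
  p$class <- cls[p$gene]
  c(homeostatic = sum(p$weight[p$class %in% "homeostatic"], na.rm = TRUE),
    inflammatory = sum(p$weight[p$class %in% "inflammatory"], na.rm = TRUE))
}

#' Generate a synthetic single-cell expression dataset
#'
#' Draws cell types from the profile proportions and gene counts from a
#' negative binomial with type-specific programmed means (plus
#' `background_genes` housekeeping genes at `background_mean`), giving a
#' deterministic function of `(profile, n_cells, seed)`.
#'
#' @param profile an [entity_profile()] (or a compatible list).
#' @param n_cells number of cells, at least 50.
#' @param seed integer seed.
#' @param sample_id sample label attached to every cell; defaults to
#'   `"<entity>_s<seed>"`.
#' @return A list with `expression` (raw-count [gene_expression()]), `cells`
#'   (data.frame `cell_id`, `sample_id`, `entity`, `cell_type`,
#'   `compartment`) and `truth` (the program table used).
#' @export
generate_expression <- function(profile, n_cells, seed = 1,
                                sample_id = NULL) {
  if (n_cells < 50) stop("n_cells must be at least 50")
  props <- profile$proportions
  if (abs(sum(props) - 1) > 1e-9)
    stop("cell type proportions must sum to 1")
  if (is.null(sample_id))
    sample_id <- sprintf("%s_s%d", profile$entity, as.integer(seed))

  withr::with_seed(as.integer(seed), {
    types <- sample(names(props), n_cells, replace = TRUE, prob = props)
    genes <- sort(unique(c(profile$programs$gene, profile$zero_genes)))
    bg <- sprintf("BG%03d", seq_len(profile$background_genes))
    all_genes <- c(genes, bg)
    mu <- matrix(0, nrow = length(all_genes), ncol = n_cells,
                 dimnames = list(all_genes, NULL))
    mu[bg, ] <- profile$background_mean
    for (i in seq_len(nrow(profile$programs))) {
      pr <- profile$programs[i, ]
      idx <- which(types == pr$cell_type)
      if (!length(idx)) next
      if (pr$fraction < 1) {
        keep <- runif(length(idx)) < pr$fraction
        idx <- idx[keep]
        if (!length(idx)) next
      }
      mu[pr$gene, idx] <- mu[pr$gene, idx] + pr$mean
    }
    counts <- matrix(rnbinom(length(mu), mu = mu, size = profile$dispersion),
                     nrow = nrow(mu))
    counts[mu == 0] <- 0L
    cell_ids <- sprintf("%s_c%05d", sample_id, seq_len(n_cells))
    expr <- gene_expression(counts, all_genes, cell_ids, normalized = FALSE)
    cells <- data.frame(cell_id = cell_ids, sample_id = sample_id,
                        entity = profile$entity, cell_type = types,
                        compartment = compartment_of(types),
                        stringsAsFactors = FALSE)
    list(expression = expr, cells = cells, truth = profile$programs)
  })
}

#' Spatial layout configuration
#'
#' Describes the synthetic tissue geometry: a rectangular field with circular
#' B cell follicles (FDC-rich cores ringed by B cells with T_FH admixture)
#' embedded in a T-zone of T cells and FRCs, optionally a subcapsular
#' sinus band of macrophages and lymphatic endothelium; or, with
#' `diffuse = TRUE`, a fully mixed field emulating the effaced DLBCL
#' architecture.
#'
#' @param field_size_um width/height of the field in microns.
#' @param follicles data.frame with columns `x`, `y`, `r`, `core_r`
#'   (centers, follicle radius, FDC core radius, all microns). Discs must lie
#'   inside the field.
#' @param sinus_band optional `c(ymin, ymax)` horizontal band.
#' @param diffuse logical; mix all cell types uniformly.
#' @param density_per_um2 expected cells per square micron.
#' @param intensity_model data.frame per marker with log-normal negative and
#'   positive component parameters and the positive cell types
#'   (columns `marker`, `pos_types` (semicolon-separated), `neg_meanlog`,
#'   `neg_sdlog`, `pos_meanlog`, `pos_sdlog`).
#' @return A list of class `spatial_layout`.
#' @export
spatial_layout <- function(field_size_um = c(1000, 1000),
                           follicles = data.frame(
                             x = c(250, 700), y = c(700, 750),
                             r = c(150, 130), core_r = c(60, 50)),
                           sinus_band = c(0, 80),
                           diffuse = FALSE,
                           density_per_um2 = 0.002,
                           intensity_model = default_intensity_model()) {
  if (density_per_um2 <= 0) stop("density_per_um2 must be positive")
  if (!diffuse && nrow(follicles)) {
    inside <- follicles$x - follicles$r >= 0 &
      follicles$x + follicles$r <= field_size_um[1] &
      follicles$y - follicles$r >= 0 &
      follicles$y + follicles$r <= field_size_um[2]
    if (!all(inside)) stop("follicle discs must lie inside the field")
    if (any(follicles$core_r >= follicles$r))
      stop("follicle core radius must be smaller than the follicle radius")
  }
  im <- intensity_model
  if (any(im$pos_meanlog <= im$neg_meanlog))
    stop("positive component mean must exceed negative component mean")
  structure(list(field_size_um = field_size_um, follicles = follicles,
                 sinus_band = sinus_band, diffuse = diffuse,
                 density_per_um2 = density_per_um2,
                 intensity_model = im),
            class = "spatial_layout")
}

#' Default bimodal marker intensity model
#'
#' Two log-normal components per marker; the positive component applies to
#' the lineage-appropriate cell types (CD21 on FDC, PDPN on FDC/FRC/LEC,
#' CD31 on endothelium, CD20 on B cells, CD3 on T cells).
#'
#' @return A data.frame usable as `intensity_model` in [spatial_layout()].
#' @export
default_intensity_model <- function() {
  data.frame(
    marker = c("CD21", "PDPN", "CD31", "CD20", "CD3"),
    pos_types = c("FDC", "FDC;FRC;rFRC;LEC", "BEC;LEC", "B",
                  "T_H;T_FH;T_tox;T_reg"),
    neg_meanlog = 1, neg_sdlog = 0.5,
    pos_meanlog = 4, pos_sdlog = 0.5,
    stringsAsFactors = FALSE)
}

## zone-conditional cell type mixtures for structured layouts
zone_composition <- function(zone, profile) {
  switch(zone,
    follicle_core = c(FDC = 0.45, B = 0.45, T_FH = 0.10),
    follicle_ring = c(B = 0.80, T_FH = 0.12, T_H = 0.05, FDC = 0.03),
    t_zone = c(T_H = 0.40, T_tox = 0.18, T_reg = 0.08, FRC = 0.14,
               B = 0.10, Macro = 0.06, BEC = 0.04),
    sinus = c(Macro = 0.50, LEC = 0.35, B = 0.10, T_H = 0.05),
    diffuse = profile$proportions,
    stop("unknown zone: ", zone))
}

#' Generate a synthetic segmented spatial cell table
#'
#' Places cells by a homogeneous Poisson process over the field, assigns the
#' zone of each point from the layout geometry (follicle core/ring, T zone,
#' sinus; or a single diffuse zone), draws the cell type from the
#' zone-conditional mixture, marker intensities from the two-component
#' log-normal model, and per-gene transcript counts from the entity's
#' chemokine program (scaled to imaging-panel depth).
#'
#' @param layout a [spatial_layout()].
#' @param profile an [entity_profile()]; supplies type programs for
#'   transcripts and the diffuse-mode mixture.
#' @param seed integer seed.
#' @param transcript_scale multiplier applied to programmed means for the
#'   transcript panel (default 0.5).
#' @return A data.frame with columns `cell_id`, `x_um`, `y_um`, `cell_type`,
#'   `zone` (planted truth: `follicle`, `t_zone`, `sinus` or `diffuse`),
#'   `marker_*` intensity columns, `count_*` transcript columns and
#'   `total_transcripts`.
#' @export
generate_spatial <- function(layout, profile, seed = 1,
                             transcript_scale = 0.5) {
  withr::with_seed(as.integer(seed), {
    area <- prod(layout$field_size_um)
    n <- rpois(1, layout$density_per_um2 * area)
    if (n < 1) stop("layout density produced no cells")
    x <- runif(n, 0, layout$field_size_um[1])
    y <- runif(n, 0, layout$field_size_um[2])

    if (layout$diffuse) {
      zone_fine <- rep("diffuse", n)
    } else {
      zone_fine <- rep("t_zone", n)
      if (!is.null(layout$sinus_band))
        zone_fine[y >= layout$sinus_band[1] &
                    y <= layout$sinus_band[2]] <- "sinus"
      for (i in seq_len(nrow(layout$follicles))) {
        f <- layout$follicles[i, ]
        d2 <- (x - f$x)^2 + (y - f$y)^2
        zone_fine[d2 <= f$r^2] <- "follicle_ring"
        zone_fine[d2 <= f$core_r^2] <- "follicle_core"
      }
    }
    types <- character(n)
    for (z in unique(zone_fine)) {
      comp <- zone_composition(z, profile)
      idx <- which(zone_fine == z)
      types[idx] <- sample(names(comp), length(idx), replace = TRUE,
                           prob = comp)
    }
    zone <- ifelse(zone_fine %in% c("follicle_core", "follicle_ring"),
                   "follicle", zone_fine)

    out <- data.frame(cell_id = sprintf("sp_c%05d", seq_len(n)),
                      x_um = x, y_um = y, cell_type = types, zone = zone,
                      stringsAsFactors = FALSE)

    im <- layout$intensity_model
    for (i in seq_len(nrow(im))) {
      pos_types <- strsplit(im$pos_types[i], ";")[[1]]
      is_pos <- types %in% pos_types
      v <- numeric(n)
      v[is_pos] <- rlnorm(sum(is_pos), im$pos_meanlog[i], im$pos_sdlog[i])
      v[!is_pos] <- rlnorm(sum(!is_pos), im$neg_meanlog[i], im$neg_sdlog[i])
      out[[paste0("marker_", im$marker[i])]] <- v
    }

    genes <- sort(unique(c(profile$programs$gene, profile$zero_genes)))
    mu <- matrix(0, nrow = n, ncol = length(genes),
                 dimnames = list(NULL, genes))
    for (i in seq_len(nrow(profile$programs))) {
      pr <- profile$programs[i, ]
      idx <- which(types == pr$cell_type)
      if (!length(idx)) next
      if (pr$fraction < 1) idx <- idx[runif(length(idx)) < pr$fraction]
      if (!length(idx)) next
      mu[idx, pr$gene] <- mu[idx, pr$gene] + pr$mean * transcript_scale
    }
    counts <- matrix(rnbinom(length(mu), mu = mu, size = profile$dispersion),
                     nrow = n)
    counts[mu == 0] <- 0L
    bg_counts <- matrix(rpois(n * 20L, 4), nrow = n)
    colnames(counts) <- paste0("count_", genes)
    out <- cbind(out, counts)
    out$total_transcripts <- rowSums(counts) + rowSums(bg_counts)
    out
  })
}

#' Generate a synthetic survival cohort
#'
#' Signature scores are standard normal; subjects whose score falls below the
#' planted `cutpoint_quantile` have their exponential event hazard multiplied
#' by `exp(effect)` (so `effect = log(3)` plants a hazard ratio of 3 for the
#' low-signature group, emulating the adverse effect of losing homeostatic
#' chemokine expression). Independent uniform censoring is calibrated to the
#' requested censoring fraction.
#'
#' @param n subjects, at least 20.
#' @param effect log hazard ratio applied below the cutpoint
#'   (default `log(3)`).
#' @param censor_fraction target fraction of censored subjects in `[0, 1)`.
#' @param cutpoint_quantile planted cutpoint as a quantile of the score
#'   distribution, in (0, 1).
#' @param seed integer seed.
#' @param base_hazard baseline exponential hazard per month
#'   (default `log(2)/60`: 60-month median survival in the high group).
#' @return A data.frame (`subject_id`, `time` in months, `event`, `score`,
#'   `true_group`) with the planted cutpoint in `attr(, "cutpoint")`.
#' @export
generate_survival <- function(n, effect = log(3), censor_fraction = 0.2,
                              cutpoint_quantile = 0.6, seed = 1,
                              base_hazard = log(2) / 60) {
  if (n < 20) stop("n must be at least 20")
  if (censor_fraction < 0 || censor_fraction >= 1)
    stop("censor_fraction must lie in [0, 1)")
  if (cutpoint_quantile <= 0 || cutpoint_quantile >= 1)
    stop("cutpoint_quantile must lie in (0, 1)")
  cutpoint <- stats::qnorm(cutpoint_quantile)
  withr::with_seed(as.integer(seed), {
    score <- rnorm(n)
    low <- score < cutpoint
    hazard <- ifelse(low, base_hazard * exp(effect), base_hazard)
    t_event <- rexp(n, rate = hazard)
    if (censor_fraction > 0) {
      ## P(censored) for C ~ U(0, b) against the exponential mixture
      p_low <- cutpoint_quantile
      pcens <- function(b) {
        intsurv <- p_low * (1 - exp(-base_hazard * exp(effect) * b)) /
          (base_hazard * exp(effect)) +
          (1 - p_low) * (1 - exp(-base_hazard * b)) / base_hazard
        intsurv / b
      }
      b <- uniroot(function(b) pcens(b) - censor_fraction,
                   lower = 1e-6, upper = 1e6, tol = 1e-8)$root
      t_cens <- runif(n, 0, b)
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    } else {
      event <- rep(1L, n)
      time <- t_event
    }
    out <- data.frame(subject_id = sprintf("pt%04d", seq_len(n)),
                      time = time, event = event, score = score,
                      true_group = ifelse(low, "low", "high"),
                      stringsAsFactors = FALSE)
    attr(out, "cutpoint") <- cutpoint
    out
  })
}
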