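#' Configuration for a full study analysis
#'
#' @param study_dir Directory produced by [make_study()] (or laid out the
#'   same way: NIfTI scans + sidecars, `study_manifest.tsv`, atlas files).
#' @param out_dir Output directory for tables, maps and provenance.
#' @param stat A [stat_config()].
#' @param seeds Sinus seed tibble (see [default_sss_seeds()]).
#' @param scan_types Named list describing each scan type's geometry (as in
#'   [make_study()]); used for gap masks and slice-axis orientation.
#' @param stages Subset of
#'   `c("region_stats", "vbm", "sss", "gap_qc")` to run (normalization is
#'   performed, or reloaded from `out_dir/normalized`, whenever needed).
#' @param transforms `"estimate"` to estimate the normalization chain by
#'   registration (skull-strip, rigid-to-baseline, affine-to-reference,
#'   affine-to-atlas), or `"truth"` to use the generator's recorded poses (a
#'   validation mode for simulation studies).
#' @param vbm_modalities Modalities to run VBM on.
#' @param region_modality Modality for region-based tests.
#' @param target_mean Global mean-intensity rescaling target.
#' @param smooth_sigma `c(in_plane, through_plane)` smoothing sigmas (mm).
#' @param reference_subject Subject id whose B1 scan anchors the common
#'   space (default: first subject).
#' @param rng_seed Master seed; per-stage seeds are derived by stable
#'   hashing of the stage name.
#' @param max_reg_iter Registration iteration cap (lower for quick runs).
#' @return An object of class `study_config`.
#' @export
study_config <- function(study_dir, out_dir,
                         stat = stat_config(),
                         seeds = default_sss_seeds(),
                         scan_types = default_scan_types(),
                         stages = c("region_stats", "vbm", "sss", "gap_qc"),
                         transforms = c("estimate", "truth"),
                         vbm_modalities = c("T2W", "GRE_DIFF"),
                         region_modality = "T2W",
                         target_mean = 1000,
                         smooth_sigma = c(0.2734, 1.5),
                         reference_subject = NULL,
                         rng_seed = 1L,
                         max_reg_iter = 120L) {
  transforms <- match.arg(transforms)
  structure(
    list(study_dir = study_dir, out_dir = out_dir, stat = stat,
         seeds = seeds, scan_types = scan_types, stages = stages,
         transforms = transforms, vbm_modalities = vbm_modalities,
         region_modality = region_modality, target_mean = target_mean,
         smooth_sigma = smooth_sigma, reference_subject = reference_subject,
         rng_seed = as.integer(rng_seed), max_reg_iter = max_reg_iter),
    class = "study_config"
  )
}

#' Validate a study configuration
#'
#' Checks invariants (thresholds in range, referenced files present, day
#' labels known, group sizes at least 2) and returns the violations.
#'
#' @param cfg A [study_config()] (or a named list / YAML-loaded equivalent).
#' @return Tibble of violations (zero rows when valid).
#' @export
validate_config <- function(cfg) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  for (f in c("alpha_fdr", "alpha_cluster", "p_voxel")) {
    val <- cfg$stat[[f]]
    chk(is.numeric(val) && val > 0 && val < 1,
        sprintf("stat$%s must be in (0, 1), got %s", f, format(val)))
  }
  chk(cfg$stat$n_permutations >= 100,
      "stat$n_permutations must be >= 100")
  chk(dir.exists(cfg$study_dir),
      sprintf("study_dir does not exist: %s", cfg$study_dir))
  mpath <- file.path(cfg$study_dir, "study_manifest.tsv")
  chk(file.exists(mpath), sprintf("manifest not found: %s", mpath))
  ok_stages <- c("region_stats", "vbm", "sss", "gap_qc")
  chk(all(cfg$stages %in% ok_stages),
      sprintf("unknown stage(s): %s",
              paste(setdiff(cfg$stages, ok_stages), collapse = ", ")))
  if (file.exists(mpath)) {
    man <- utils::read.delim(mpath, stringsAsFactors = FALSE)
    bad_days <- setdiff(unique(man$day), study_days())
    chk(length(bad_days) == 0,
        sprintf("unknown day label(s): %s", paste(bad_days, collapse = ", ")))
    missing <- man$file[!file.exists(file.path(cfg$study_dir, man$file))]
    for (f in missing)
      v <- c(v, sprintf("manifest references a missing file: %s", f))
    counts <- table(man$day[man$scan_type == cfg$region_modality])
    if (length(counts) && any(counts < 2))
      v <- c(v, "each day group needs at least 2 scans")
  }
  tibble(violation = v)
}

read_study_atlas <- function(study_dir) {
  labv <- read_volume(file.path(study_dir, "atlas_labels.nii.gz"))
  maskv <- read_volume(file.path(study_dir, "atlas_mask.nii.gz"))
  regions <- as_tibble(utils::read.delim(
    file.path(study_dir, "atlas_regions.tsv"), stringsAsFactors = FALSE))
  frame <- bregma_frame(unlist(jsonlite::read_json(
    file.path(study_dir, "frame.json"), simplifyVector = TRUE)))
  template <- read_volume(file.path(study_dir, "template.nii.gz"))
  atlas <- label_volume(array(as.integer(round(labv$data)), dim(labv$data)),
                        maskv$data > 0.5, labv$affine, regions)
  list(atlas = atlas, frame = frame, template = template)
}

#' Run the full study analysis
#'
#' Orchestrates the end-to-end pipeline on a synthetic (or equivalently
#' organised) study: skull-stripping, bias correction, spatial
#' normalization with intensity rescaling, contrast difference images,
#' then the requested analysis stages (region statistics, VBM, sinus
#' diameters, slice-gap QC). Normalized volumes are cached under
#' `out_dir/normalized` and reused on reruns, which also makes partial
#' stage runs cheap. All stochastic steps derive their seeds from
#' `cfg$rng_seed`, so reruns with the same config are bit-identical.
#'
#' @param cfg A [study_config()].
#' @return A list of stage outputs (tibbles and result objects), invisibly;
#'   tables are also written as TSV under `cfg$out_dir`.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  viol <- validate_config(cfg)
  if (nrow(viol))
    stop("invalid config:\n", paste(viol$violation, collapse = "\n"),
         call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  ctx <- new.env(parent = emptyenv())
  ctx$ref <- read_study_atlas(cfg$study_dir)
  ctx$manifest <- as_tibble(utils::read.delim(
    file.path(cfg$study_dir, "study_manifest.tsv"),
    stringsAsFactors = FALSE))
  norm <- normalize_study(cfg, ctx)
  out <- list(normalized = norm$index)
  if ("region_stats" %in% cfg$stages)
    out$region_stats <- stage_region_stats(cfg, ctx, norm)
  if ("vbm" %in% cfg$stages)
    out$vbm <- stage_vbm(cfg, ctx, norm)
  if ("sss" %in% cfg$stages)
    out$sss <- stage_sss(cfg, ctx, norm)
  if ("gap_qc" %in% cfg$stages)
    out$gap_qc <- stage_gap_qc(cfg, ctx, norm, out$vbm)
  prov <- list(rng_seed = cfg$rng_seed, transforms = cfg$transforms,
               stages = cfg$stages,
               package_version = as.character(utils::packageVersion("ratvbm")))
  jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

# normalize every scan (and GRE difference pairs) into atlas space,
# caching results on disk
normalize_study <- function(cfg, ctx) {
  man <- ctx$manifest
  atlas <- ctx$ref$atlas
  ndir <- file.path(cfg$out_dir, "normalized")
  dir.create(ndir, recursive = TRUE, showWarnings = FALSE)
  geoms <- lapply(cfg$scan_types, function(s) s$geom)
  chains <- if (cfg$transforms == "estimate")
    estimate_chains(cfg, ctx) else NULL
  index <- list(); vols <- list(); valid <- list()
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    key <- sub("\\.nii(\\.gz)?$", "", row$file)
    cache <- file.path(ndir, paste0(key, "_norm.nii.gz"))
    vcache <- file.path(ndir, paste0(key, "_valid.nii.gz"))
    geom <- geoms[[row$type_name]]
    if (file.exists(cache) && file.exists(vcache)) {
      nv <- read_volume(cache, modality = row$scan_type)
      vv <- read_volume(vcache)
      attr(nv, "validity") <- vv$data > 0.5
    } else {
      scan <- read_volume(file.path(cfg$study_dir, row$file),
                          modality = row$scan_type)
      M <- if (cfg$transforms == "truth") solve(manifest_pose(row))
           else chains[[row$file]]
      mres <- resample_array(atlas$brain_mask + 0,
                             solve(M) %*% atlas$affine, scan$affine,
                             dim(scan$data), "nearest")
      mask <- mres$data > 0.5
      if (sum(mask) > 32) {
        bc <- correct_bias_field(scan, mask)
        scan <- rescale_mean_intensity(bc$corrected, mask, cfg$target_mean)
      }
      nv <- normalize_to_atlas(scan, M, atlas, geom = geom)
      write_volume(nv, cache)
      write_volume(volume_image(attr(nv, "validity") + 0, nv$affine),
                   vcache)
    }
    vols[[row$file]] <- nv
    valid[[row$file]] <- attr(nv, "validity")
    index[[length(index) + 1]] <- tibble(
      file = row$file, subject = row$subject, day = row$day,
      scan_type = row$scan_type, type_name = row$type_name,
      cached = cache)
  }
  # contrast difference images from normalized pre/post pairs (same grid,
  # already aligned through their chains, so the subtraction is voxelwise)
  pre <- man[man$scan_type == "GRE_PRE", ]
  post <- man[man$scan_type == "GRE_POST", ]
  for (i in seq_len(nrow(pre))) {
    j <- which(post$subject == pre$subject[i] & post$day == pre$day[i])
    if (length(j) != 1) next
    key <- sprintf("%s_%s_GRE_diff", pre$subject[i], pre$day[i])
    a <- vols[[post$file[j]]]; b <- vols[[pre$file[i]]]
    dv <- volume_image(a$data - b$data, a$affine, "GRE_DIFF")
    vj <- valid[[post$file[j]]] & valid[[pre$file[i]]]
    attr(dv, "validity") <- vj
    fn <- paste0(key, ".nii.gz")
    vols[[fn]] <- dv
    valid[[fn]] <- vj
    index[[length(index) + 1]] <- tibble(
      file = fn, subject = pre$subject[i], day = pre$day[i],
      scan_type = "GRE_DIFF", type_name = "GRE_diff", cached = NA_character_)
  }
  list(index = dplyr::bind_rows(index), vols = vols, valid = valid)
}

# estimate scan -> atlas world maps following the normalization design:
# post-injury/B2 scans rigid to the subject's B1, subject B1 affine to the
# reference subject's B1, reference B1 affine to the atlas template
estimate_chains <- function(cfg, ctx) {
  man <- ctx$manifest
  template <- ctx$ref$template
  atlas <- ctx$ref$atlas
  ref_sub <- cfg$reference_subject %||% sort(unique(man$subject))[1]
  anchor_type <- if (cfg$region_modality %in% man$scan_type)
    cfg$region_modality else man$scan_type[1]
  read_scan <- function(row) read_volume(file.path(cfg$study_dir, row$file),
                                         modality = row$scan_type)
  b1 <- man[man$day == "B1" & man$scan_type == anchor_type, ]
  ref_row <- b1[b1$subject == ref_sub, ]
  ref_img <- read_scan(ref_row[1, ])
  M_ref_atlas <- register_affine(ref_img, template,
                                 max_iter = cfg$max_reg_iter)
  chains <- list()
  for (sub in unique(man$subject)) {
    sub_b1 <- b1[b1$subject == sub, ][1, ]
    b1_img <- read_scan(sub_b1)
    M_b1_ref <- if (sub == ref_sub) diag(4)
                else register_affine(b1_img, ref_img,
                                     max_iter = cfg$max_reg_iter)
    rows <- man[man$subject == sub, ]
    for (i in seq_len(nrow(rows))) {
      row <- rows[i, ]
      M_scan_b1 <- if (row$day == "B1") diag(4)
      else {
        img <- read_scan(row)
        register_rigid(img, b1_img, max_iter = cfg$max_reg_iter)
      }
      ch <- compose_chain(scan_to_B1 = unclass_matrix(M_scan_b1),
                          B1_to_ref = unclass_matrix(M_b1_ref),
                          ref_to_atlas = unclass_matrix(M_ref_atlas))
      chains[[row$file]] <- ch$composite
      write_chain(ch, file.path(cfg$out_dir, "normalized",
                                sub("\\.nii(\\.gz)?$", "_chain.json",
                                    row$file)))
    }
  }
  chains
}

post_days <- function(days) intersect(c("P1", "P2", "P7", "P14"),
                                      unique(days))

stage_region_stats <- function(cfg, ctx, norm) {
  idx <- norm$index[norm$index$scan_type == cfg$region_modality, ]
  atlas <- ctx$ref$atlas
  rm_mat <- function(rows) {
    t(vapply(rows$file, function(f)
      region_means(norm$vols[[f]], atlas, norm$valid[[f]])$mean,
      numeric(nrow(atlas$region_names))))
  }
  base <- rm_mat(idx[idx$day %in% c("B1", "B2"), ])
  out <- list()
  for (day in post_days(idx$day)) {
    dm <- rm_mat(idx[idx$day == day, ])
    out[[day]] <- region_group_test(base, dm, cfg$stat,
                                    region_names = atlas$region_names,
                                    contrast = paste0(day, "_vs_B"))
  }
  tab <- dplyr::bind_rows(out)
  utils::write.table(tab, file.path(cfg$out_dir, "region_stats.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  tab
}

stage_vbm <- function(cfg, ctx, norm) {
  atlas <- ctx$ref$atlas
  frame <- ctx$ref$frame
  results <- list()
  for (mod in intersect(cfg$vbm_modalities, norm$index$scan_type)) {
    idx <- norm$index[norm$index$scan_type == mod, ]
    ax <- 2L  # axial default; sagittal scan types would use 1L
    smooth_all <- function(rows) lapply(rows$file, function(f)
      smooth_gaussian(norm$vols[[f]], cfg$smooth_sigma, through_axis = ax))
    base <- smooth_all(idx[idx$day %in% c("B1", "B2"), ])
    for (day in post_days(idx$day)) {
      contrast <- sprintf("%s_%s_vs_B", mod, day)
      res <- vbm_contrast(
        smooth_all(idx[idx$day == day, ]), base, atlas$brain_mask, atlas,
        frame, cfg$stat, contrast,
        rng_seed = stable_seed(cfg$rng_seed, paste0("vbm/", contrast)))
      results[[contrast]] <- res
    }
  }
  tab <- dplyr::bind_rows(lapply(results, tidy))
  utils::write.table(tab, file.path(cfg$out_dir, "vbm_clusters.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  list(results = results, table = tab)
}

stage_sss <- function(cfg, ctx, norm) {
  idx <- norm$index[norm$index$scan_type == "GRE_DIFF", ]
  if (nrow(idx) == 0) return(NULL)
  scans <- tibble(subject = idx$subject, day = idx$day,
                  scan = lapply(idx$file, function(f) norm$vols[[f]]))
  meas <- measure_study_sss(scans, ctx$ref$frame, cfg$seeds)
  meas$day_group <- ifelse(meas$day %in% c("B1", "B2"), "B", meas$day)
  tbl <- dplyr::rename(meas, scan_day = "day")
  tbl$day <- tbl$day_group
  ana <- diameter_group_analysis(tbl, alpha = 0.05)
  utils::write.table(meas, file.path(cfg$out_dir, "sss_diameters.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(ana$pairwise,
                     file.path(cfg$out_dir, "sss_pairwise.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  list(measurements = meas, analysis = ana)
}

stage_gap_qc <- function(cfg, ctx, norm, vbm_out) {
  man <- ctx$manifest
  atlas <- ctx$ref$atlas
  reports <- list(); maps <- list()
  for (tn in unique(man$type_name)) {
    geom <- cfg$scan_types[[tn]]$geom
    if (is.null(geom) || slice_gap(geom) <= 0) next
    rows <- man[man$type_name == tn, ]
    masks <- lapply(seq_len(nrow(rows)), function(i) {
      f <- rows$file[i]
      v <- norm$valid[[f]]
      # gap voxels were flagged invalid during normalization
      array(!v, dim = dim(atlas$labels)) & atlas$brain_mask
    })
    om <- overlap_map(masks, affine = atlas$affine)
    maps[[tn]] <- om
    write_volume(volume_image(om$counts + 0, atlas$affine),
                 file.path(cfg$out_dir, paste0("gap_overlap_", tn,
                                               ".nii.gz")))
    mod <- cfg$scan_types[[tn]]$modality
    if (!is.null(vbm_out)) {
      for (nm in names(vbm_out$results)) {
        if (!startsWith(nm, mod)) next
        rep <- striping_check(vbm_out$results[[nm]]$t_map, om,
                              axis = slice_axis(geom),
                              period_mm = geom$slice_spacing,
                              spacing_mm = voxel_spacing(
                                list(affine = atlas$affine))[
                                  slice_axis(geom)])
        reports[[paste0(tn, "/", nm)]] <- rep
      }
    }
  }
  qc <- dplyr::bind_rows(lapply(names(reports), function(nm) tibble(
    contrast = nm,
    profile_correlation = reports[[nm]]$profile_correlation,
    power_t = reports[[nm]]$power_t,
    power_overlap = reports[[nm]]$power_overlap)))
  if (nrow(qc))
    utils::write.table(qc, file.path(cfg$out_dir, "gap_qc.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  list(overlap_maps = maps, reports = reports, table = qc)
}
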