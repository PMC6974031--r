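#' Write a synthetic dataset to disk in standard formats
#'
#' Layout (BIDS-flavored): per subject, `sub-XX/func/` holds one events
#' TSV, one 4-D BOLD NIfTI per ROI and a nuisance TSV per run; masks go to
#' `masks/`, per-subject ground truth (without latent patterns) and the
#' recognition counts to JSON/TSV, and the generating config to
#' `config.json`.
#'
#' @param dataset an `sp_dataset`.
#' @param dir output directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- dataset$config
  jsonlite::write_json(cfg_summary(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  mdir <- file.path(dir, "masks")
  dir.create(mdir, showWarnings = FALSE)
  for (rn in names(dataset$masks)) {
    m <- dataset$masks[[rn]]
    vol <- array(0L, dim = m$dims)
    vol[m$indices] <- 1L
    write_nifti(vol, file.path(mdir, sprintf("roi-%s_mask.nii", rn)),
                voxel_size_mm = m$voxel_size_mm, affine = m$affine,
                datatype = "uint8")
  }
  phase_tag <- c(preconditioning = "precond", conditioning = "cond",
                 probe = "probe")
  for (s in seq_along(dataset$subjects)) {
    sub <- dataset$subjects[[s]]
    sdir <- file.path(dir, sprintf("sub-%02d", s), "func")
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    for (phase in names(sub$events)) {
      for (r in seq_along(sub$events[[phase]])) {
        stem <- sprintf("sub-%02d_task-%s_run-%d", s, phase_tag[[phase]], r)
        write_events(sub$events[[phase]][[r]],
                     file.path(sdir, paste0(stem, "_events.tsv")))
        data.table::fwrite(
          as.data.frame(sub$nuisance[[phase]][[r]]),
          file.path(sdir, paste0(stem, "_nuisance.tsv")), sep = "\t")
        for (rn in names(sub$bold[[phase]][[r]])) {
          m <- dataset$masks[[rn]]
          bold <- sub$bold[[phase]][[r]][[rn]]
          vol <- array(0, dim = c(m$dims, nrow(bold)))
          npl <- prod(m$dims)
          for (v in seq_len(nrow(bold)))
            vol[(v - 1) * npl + m$indices] <- bold[v, ]
          write_nifti(vol, file.path(sdir, paste0(stem, "_roi-", rn, "_bold.nii")),
                      voxel_size_mm = m$voxel_size_mm, tr_s = cfg$tr_s,
                      affine = m$affine)
        }
      }
    }
    gt <- sub$ground_truth
    gt$latents <- NULL
    jsonlite::write_json(gt, file.path(dir, sprintf("sub-%02d", s),
                                       "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    data.table::fwrite(sub$behavior$recognition,
                       file.path(dir, sprintf("sub-%02d", s), "recognition.tsv"),
                       sep = "\t")
  }
  invisible(dir)
}

#' Load a dataset written by [write_dataset()]
#'
#' Reconstructs an `sp_dataset` (without latent ground-truth patterns)
#' from the on-disk standard formats, revalidating events and masks.
#'
#' @param dir dataset directory.
#' @export
load_dataset <- function(dir) {
  cfgfile <- file.path(dir, "config.json")
  if (!file.exists(cfgfile)) abort_validation("no config.json in %s", dir)
  cfg <- sim_config_from_list(jsonlite::read_json(cfgfile, simplifyVector = TRUE))
  masks <- list()
  for (f in list.files(file.path(dir, "masks"), pattern = "_mask\\.nii",
                       full.names = TRUE)) {
    rn <- sub("^roi-(.*)_mask\\.nii(\\.gz)?$", "\\1", basename(f))
    masks[[rn]] <- read_volume(f, expect_4d = FALSE, name = rn)
  }
  masks <- masks[names(cfg$rois)]
  phase_tag <- c(preconditioning = "precond", conditioning = "cond",
                 probe = "probe")
  sub_dirs <- sort(list.dirs(dir, recursive = FALSE))
  sub_dirs <- sub_dirs[grepl("sub-\\d+$", sub_dirs)]
  subjects <- lapply(seq_along(sub_dirs), function(s) {
    sdir <- file.path(sub_dirs[s], "func")
    events <- list(); bold <- list(); nuis <- list(); nvols <- list()
    for (phase in names(phase_tag)) {
      events[[phase]] <- list(); bold[[phase]] <- list()
      nuis[[phase]] <- list(); nvols[[phase]] <- list()
      for (r in seq_len(cfg$runs[[phase]])) {
        stem <- sprintf("%s_task-%s_run-%d", basename(sub_dirs[s]),
                        phase_tag[[phase]], r)
        events[[phase]][[r]] <- read_events(
          file.path(sdir, paste0(stem, "_events.tsv")))
        nuis[[phase]][[r]] <- as.matrix(data.table::fread(
          file.path(sdir, paste0(stem, "_nuisance.tsv"))))
        bold[[phase]][[r]] <- list()
        for (rn in names(masks)) {
          vol <- read_volume(file.path(sdir, paste0(stem, "_roi-", rn, "_bold.nii")),
                             expect_4d = TRUE)
          nv <- vol$dims[4]
          npl <- prod(vol$dims[1:3])
          flat <- matrix(vol$data, nrow = npl, ncol = nv)
          bold[[phase]][[r]][[rn]] <- t(flat[masks[[rn]]$indices, , drop = FALSE])
        }
        nvols[[phase]][[r]] <- nrow(bold[[phase]][[r]][[1]])
      }
    }
    gt <- jsonlite::read_json(file.path(sub_dirs[s], "ground_truth.json"),
                              simplifyVector = TRUE)
    recog <- as.data.frame(data.table::fread(
      file.path(sub_dirs[s], "recognition.tsv")))
    list(subject = s, events = events, bold = bold, nuisance = nuis,
         n_volumes = nvols, behavior = list(recognition = recog,
                                            d_prime = gt$d_prime),
         ground_truth = gt)
  })
  structure(list(config = cfg, masks = masks, subjects = subjects),
            class = "sp_dataset")
}
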