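# Shared fixture builders: small designs and matrices constructed in code.

# OmicsMatrix straight from a values matrix; columns get condition labels
# like "high_24" (NA for pool/empty classes), one plex unless given.
makeTestMatrix <- function(values, conditions, plex = "p1",
                           classes = "sample", sample_ids = NULL,
                           scale = "log2", steps = character()) {
  n <- ncol(values)
  conditions <- rep_len(conditions, n)
  plex <- rep_len(plex, n)
  classes <- rep_len(classes, n)
  rep_idx <- stats::ave(seq_len(n), conditions, classes, FUN = seq_along)
  if (is.null(sample_ids))
    sample_ids <- ifelse(classes == "empty", NA_character_,
                         ifelse(is.na(conditions), paste0("pool_", rep_idx),
                                paste0(conditions, "_r", rep_idx)))
  channels <- data.frame(
    plex_id = plex, channel_label = paste0("ch", seq_len(n)),
    sample_id = sample_ids,
    nitrogen = ifelse(is.na(conditions), NA, sub("_.*$", "", conditions)),
    timepoint_h = ifelse(is.na(conditions), NA,
                         as.integer(sub("^.*_", "", conditions))),
    replicate = rep_idx, assay = NA_character_, channel_class = classes,
    batch = plex, condition = conditions, stringsAsFactors = FALSE)
  channels$channel_id <- paste(plex, channels$channel_label, sep = ":")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("f", seq_len(nrow(values)))
  redoxomics:::.makeOmicsMatrix(values, channels, scale = scale,
                                steps = steps)
}

asSiteMatrix <- function(m, kind = "redox") {
  methods::new("SiteMatrix", m, scale = m@scale,
               appliedSteps = m@appliedSteps, ptmKind = kind,
               adjustedForProtein = FALSE)
}

# full-width hand-built design: two plexes x 18 channels, 2 empty each
# (32 quantitative channels in total)
makeWideDesigns <- function(assay = "redox") {
  labels <- redoxomics:::TMT18_LABELS
  one <- function(phys, own_t) {
    bridge <- expand.grid(replicate = 1:3, nitrogen = c("high", "low"),
                          stringsAsFactors = FALSE)
    data.frame(
      channel_label = labels,
      sample_id = c(paste0(bridge$nitrogen, "_24_r", bridge$replicate),
                    paste0(rep(c("high", "low"), each = 3), "_", own_t,
                           "_r", rep(1:3, 2)),
                    paste0(rep(c("high", "low"), each = 1), "_", own_t,
                           "_r", 4:5),
                    "total_thiol_pool", "total_thiol_pool", NA, NA),
      nitrogen = c(bridge$nitrogen, rep(c("high", "low"), each = 3),
                   c("high", "low"), "none", "none", NA, NA),
      timepoint_h = c(rep(24L, 6), rep(own_t, 8), rep(NA_integer_, 4)),
      replicate = c(bridge$replicate, rep(1:3, 2), 4L, 5L, 1L, 2L, NA, NA),
      assay = c(rep(assay, 16), NA, NA),
      channel_class = c(rep("bridge", 6), rep("sample", 8),
                        rep("total_thiol_pool", 2), rep("empty", 2)),
      batch = c(rep(phys, 16), NA, NA), stringsAsFactors = FALSE)
  }
  list(p1 = PlexDesign("p1", one("p1", 48L)),
       p2 = PlexDesign("p2", one("p2", 72L)))
}

# tiny single-plex design for rollup arithmetic tests
makeMiniDesign <- function(n_samples = 3, condition = "high_24",
                           pools = 0, plex = "p1", assay = "global") {
  nit <- sub("_.*$", "", condition)
  tp <- as.integer(sub("^.*_", "", condition))
  ch <- data.frame(
    channel_label = paste0("ch", seq_len(n_samples + pools)),
    sample_id = c(paste0(condition, "_r", seq_len(n_samples)),
                  rep("total_thiol_pool", pools)),
    nitrogen = c(rep(nit, n_samples), rep("none", pools)),
    timepoint_h = c(rep(tp, n_samples), rep(NA_integer_, pools)),
    replicate = c(seq_len(n_samples), seq_len(pools)[seq_len(pools) > 0]),
    assay = assay,
    channel_class = c(rep("sample", n_samples),
                      rep("total_thiol_pool", pools)),
    batch = plex, stringsAsFactors = FALSE)
  PlexDesign(plex, ch)
}

# PSM table matching makeMiniDesign channels
makeMiniPSM <- function(design, peptide, protein_id, site_keys,
                        intensities) {
  labs <- designChannels(design)$channel_label
  ints <- matrix(intensities, nrow = length(peptide), byrow = TRUE)
  colnames(ints) <- labs
  cbind(data.frame(plex_id = plexId(design), peptide = peptide,
                   protein_id = protein_id, site_keys = site_keys,
                   fdr_pass = TRUE, stringsAsFactors = FALSE),
        as.data.frame(ints))
}

quietStudy <- function(cfg) suppressMessages(simulateStudy(cfg))

# normalized global + peptide reference + redox chain for a study
runRedoxChain <- function(st, proteins = TRUE) {
  psm <- lapply(st$psm, function(x) x[x$fdr_pass, , drop = FALSE])
  glob <- suppressMessages(normalizeGlobal(psm$global, st$designs[1:2]))
  gp <- suppressMessages(
    log2Transform(rollupPeptide(psm$global, st$designs[1:2])))
  red <- suppressMessages(suppressWarnings(
    normalizePTM(psm$redox, st$designs[3:4], "redox", gp,
                 if (proteins) glob else NULL)))
  list(proteins = glob, peptides = gp, redox = red)
}
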