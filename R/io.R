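#' Parse and format PTM site keys
#'
#' Site keys follow the grammar \code{"<protein>_<AA><pos>[;<AA><pos>...]"},
#' e.g. \code{"RT_123_C48"} for a single cysteine site or
#' \code{"RT_123_S512;T513"} for a composite key whose localization is
#' ambiguous between neighbouring residues. Protein identifiers may
#' themselves contain underscores; the residue specification is the final
#' underscore-delimited segment. Positions are 1-based and must be strictly
#' increasing within a composite key.
#'
#' @param keys character vector of site-key strings.
#' @return \code{parseSiteKeys}: a list (one element per key) of lists with
#'   \code{protein_id}, \code{residues} (data.frame with \code{aa},
#'   \code{pos}) and \code{ambiguity} (TRUE for composite keys).
#'   \code{formatSiteKey} is the inverse and returns the canonical string.
#' @examples
#' parseSiteKeys("RT_123_C48")[[1]]
#' formatSiteKey("RT_123", data.frame(aa = c("S", "T"), pos = c(512, 513)))
#' @export
parseSiteKeys <- function(keys) {
  pat <- "^(.+)_([CSTY][0-9]+(?:;[CSTY][0-9]+)*)$"
  ok <- grepl(pat, keys)
  if (any(!ok))
    stop("malformed site key(s): ", paste(keys[!ok], collapse = ", "),
         call. = FALSE)
  protein <- sub(pat, "\\1", keys)
  spec <- sub(pat, "\\2", keys)
  lapply(seq_along(keys), function(i) {
    parts <- strsplit(spec[i], ";", fixed = TRUE)[[1]]
    res <- data.frame(aa = substr(parts, 1, 1),
                      pos = as.integer(substring(parts, 2)),
                      stringsAsFactors = FALSE)
    if (any(diff(res$pos) <= 0))
      stop("site key '", keys[i],
           "' has non-increasing residue positions", call. = FALSE)
    list(protein_id = protein[i], residues = res,
         ambiguity = nrow(res) > 1L)
  })
}

#' @rdname parseSiteKeys
#' @param protein_id protein identifier.
#' @param residues data.frame with columns \code{aa} and \code{pos}.
#' @export
formatSiteKey <- function(protein_id, residues) {
  paste0(protein_id, "_",
         paste0(residues$aa, residues$pos, collapse = ";"))
}

# vectorized protein-id extraction used by protein subtraction
.siteProtein <- function(keys)
  sub("^(.+)_[CSTY][0-9]+(;[CSTY][0-9]+)*$", "\\1", keys)

#' Global filtering thresholds
#'
#' Returns the threshold set used across the pipeline: BH-adjusted p cutoff,
#' minimum absolute log2 fold changes for PTM-site selection (0.8), for KEGG
#' over-representation input (1) and for MSEA input (4), the Pearson
#' correlation cutoff for the redox-lipid integration (0.80), the q-value
#' cutoff for reporting enrichments (0.2), the minimum number of biological
#' replicates for a feature to enter statistics (2) and the minimum set size
#' for enrichment (2).
#'
#' @param ... named overrides of the defaults.
#' @return a named list of class \code{"FilterConfig"}.
#' @export
filterConfig <- function(...) {
  cfg <- list(adj_p_max = 0.05, lfc_min_ptm = 0.8, lfc_min_kegg_input = 1.0,
              lfc_min_msea = 4.0, pearson_min = 0.80, q_max_enrich = 0.2,
              min_bio_reps = 2L, min_set_size = 2L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    stop("unknown FilterConfig field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  num <- unlist(cfg)
  if (any(num <= 0)) stop("all thresholds must be positive")
  if (cfg$adj_p_max > 1 || cfg$q_max_enrich > 1)
    stop("probability thresholds must lie in (0, 1]")
  structure(cfg, class = "FilterConfig")
}

#' Read and write TMT plex designs
#'
#' The design file is a UTF-8 TSV with columns \code{plex_id},
#' \code{channel_label}, \code{sample_id}, \code{nitrogen},
#' \code{timepoint_h}, \code{replicate}, \code{assay}, \code{channel_class},
#' \code{batch}; blank cells are missing. All validation problems are
#' collected and reported together, not one at a time.
#'
#' @param path file path.
#' @return \code{readDesign}: a list of \linkS4class{PlexDesign}, one per
#'   distinct \code{plex_id}, validated with \code{\link{validateDesigns}}.
#' @export
readDesign <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = c("", "NA"), check.names = FALSE)
  need <- c("plex_id", DESIGN_COLUMNS)
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("design file lacks required column(s): ",
         paste(miss, collapse = ", "))
  designs <- lapply(split(tab, tab$plex_id), function(sub) {
    PlexDesign(sub$plex_id[1], sub[, DESIGN_COLUMNS])
  })
  designs <- designs[unique(tab$plex_id)]
  validateDesigns(designs)
  designs
}

#' @rdname readDesign
#' @param designs list of \linkS4class{PlexDesign}.
#' @export
writeDesign <- function(designs, path) {
  tabs <- lapply(designs, function(d) {
    ch <- designChannels(d)
    cbind(plex_id = plexId(d), ch)
  })
  utils::write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a set of plex designs jointly
#'
#' Checks, in addition to the per-plex validity rules, the cross-plex
#' invariants: bridge channels must appear with identical sample ids in at
#' least two plexes (they are the 24 h technical replicates that anchor
#' batch correction), and every redox plex must contain at least one pooled
#' total-thiol reference channel. All violations are reported in one error.
#'
#' @param designs list of \linkS4class{PlexDesign}.
#' @return invisibly TRUE, or an error listing every violation.
#' @export
validateDesigns <- function(designs) {
  errs <- character()
  for (d in designs) {
    v <- .validPlexDesign(d)
    if (!isTRUE(v)) errs <- c(errs, v)
  }
  if (!length(errs)) {
    tab <- .designTable(designs, quantitativeOnly = FALSE)
    br <- tab[tab$channel_class == "bridge", , drop = FALSE]
    if (nrow(br)) {
      plex_per_bridge <- tapply(br$plex_id, br$sample_id,
                                function(p) length(unique(p)))
      bad <- names(plex_per_bridge)[plex_per_bridge < 2]
      if (length(bad))
        errs <- c(errs, paste0("bridge sample(s) present in only one plex: ",
                               paste(bad, collapse = ", ")))
    }
    redox <- unique(tab$plex_id[!is.na(tab$assay) & tab$assay == "redox"])
    for (p in redox) {
      sub <- tab[tab$plex_id == p, ]
      if (!any(sub$channel_class == "total_thiol_pool"))
        errs <- c(errs, paste0("redox plex '", p,
                               "' has no total_thiol_pool channel"))
    }
  }
  if (length(errs))
    stop("design validation failed:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  invisible(TRUE)
}

#' Read and write PSM-level reporter intensity tables
#'
#' A PSM table is a TSV with columns \code{plex_id}, \code{peptide},
#' \code{protein_id}, \code{site_keys} (semicolon-free canonical site key,
#' or blank for global-only peptides), \code{fdr_pass} and one intensity
#' column per channel label. Intensities are linear-scale reporter ion
#' intensities; blanks are missing. Negative intensities and intensity
#' columns absent from the design are rejected.
#'
#' @param path file path.
#' @param designs list of \linkS4class{PlexDesign} the intensities belong to.
#' @param fdrOnly drop rows with \code{fdr_pass == FALSE} (the 1\% FDR
#'   filter applied before any quantification).
#' @return data.frame with the metadata columns plus intensity columns; the
#'   retained row count is reported via \code{message}.
#' @export
readPSMTable <- function(path, designs, fdrOnly = TRUE) {
  if (!file.exists(path)) stop("PSM file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = c("", "NA"), check.names = FALSE)
  meta_cols <- c("plex_id", "peptide", "protein_id", "site_keys", "fdr_pass")
  miss <- setdiff(meta_cols, names(tab))
  if (length(miss))
    stop("PSM table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"site_keys" %in% names(tab)) tab$site_keys <- NA_character_
  tab$site_keys[is.na(tab$site_keys)] <- ""
  tab$fdr_pass <- as.logical(tab$fdr_pass)
  dtab <- .designTable(designs, quantitativeOnly = FALSE)
  int_cols <- setdiff(names(tab), meta_cols)
  unknown <- setdiff(int_cols, unique(dtab$channel_label))
  if (length(unknown))
    stop("intensity column(s) with no design row: ",
         paste(unknown, collapse = ", "))
  bad_plex <- setdiff(unique(tab$plex_id), unique(dtab$plex_id))
  if (length(bad_plex))
    stop("PSM rows reference unknown plex(es): ",
         paste(bad_plex, collapse = ", "))
  for (cc in int_cols) {
    neg <- which(!is.na(tab[[cc]]) & tab[[cc]] < 0)
    if (length(neg))
      stop("negative intensity in channel '", cc, "', row(s) ",
           paste(utils::head(neg, 5), collapse = ", "))
  }
  # validate site keys (parser raises on malformed keys)
  keyed <- tab$site_keys != ""
  if (any(keyed)) invisible(parseSiteKeys(tab$site_keys[keyed]))
  n0 <- nrow(tab)
  if (fdrOnly) tab <- tab[tab$fdr_pass, , drop = FALSE]
  message("readPSMTable: kept ", nrow(tab), " of ", n0, " PSM rows",
          if (fdrOnly) " after FDR filtering" else "")
  rownames(tab) <- NULL
  tab
}

#' @rdname readPSMTable
#' @param psm PSM data.frame as returned by \code{readPSMTable}.
#' @export
writePSMTable <- function(psm, path) {
  utils::write.table(psm, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write lipid peak-height tables
#'
#' Lipid tables are CSV with columns \code{lipid_id}, \code{class},
#' \code{subclass} followed by one column per sample. Blank cells and zeros
#' are recorded as missing (peak heights of zero mean the species was not
#' observed in that sample). Duplicate lipid ids are an error.
#'
#' @param path file path.
#' @return data.frame with annotation plus sample intensity columns
#'   (missing as NA).
#' @export
readLipidTable <- function(path) {
  if (!file.exists(path)) stop("lipid file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  need <- c("lipid_id", "class", "subclass")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("lipid table lacks column(s): ", paste(miss, collapse = ", "))
  dup <- tab$lipid_id[duplicated(tab$lipid_id)]
  if (length(dup))
    stop("duplicate lipid_id(s): ", paste(unique(dup), collapse = ", "))
  samp_cols <- setdiff(names(tab), need)
  if (!length(samp_cols)) stop("lipid table has no sample columns")
  for (cc in samp_cols) {
    v <- tab[[cc]]
    v[!is.na(v) & v == 0] <- NA_real_   # zero peak height == not observed
    if (any(!is.na(v) & v < 0))
      stop("negative peak height in sample '", cc, "'")
    tab[[cc]] <- v
  }
  rownames(tab) <- NULL
  tab
}

#' @rdname readLipidTable
#' @param lipids lipid data.frame.
#' @export
writeLipidTable <- function(lipids, path) {
  utils::write.csv(lipids, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write GMT set collections
#'
#' Standard GMT: one set per line,
#' \code{name<TAB>description<TAB>id1<TAB>id2...}. Sets with no members are
#' rejected. Membership is intersected with a declared universe at use time
#' (see \code{\link{oraHypergeometric}}), not at load time.
#'
#' @param path file path.
#' @return a named list of character vectors of member ids, with a
#'   \code{"description"} attribute (named character vector).
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 3L
  if (any(short))
    stop("GMT line(s) with fewer than one member: line ",
         paste(which(short), collapse = ", "))
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  names(desc) <- nm
  attr(sets, "description") <- desc
  sets
}

#' @rdname readGMT
#' @param sets named list of member-id vectors (optionally with a
#'   \code{description} attribute).
#' @export
writeGMT <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Lipid class identification shares
#'
#' Percent share of identified lipid species per major class, from a
#' class-count table (columns \code{class}, \code{n_species}). The package
#' ships the identification counts of the reference nitrogen-limitation
#' lipidome of \emph{R. toruloides} under
#' \code{system.file("extdata", "lipid_class_counts.tsv",
#' package = "redoxomics")}: 206 species of which 172 are combined
#' glycerophospholipids and glycerolipids.
#'
#' @param counts data.frame with \code{class} and \code{n_species}, or a
#'   path to a TSV with those columns.
#' @return named numeric vector of percentages summing to 100.
#' @export
lipidClassShares <- function(counts) {
  if (is.character(counts))
    counts <- utils::read.delim(counts, stringsAsFactors = FALSE)
  stopifnot(all(c("class", "n_species") %in% names(counts)))
  if (any(counts$n_species < 0)) stop("negative species counts")
  stats::setNames(100 * counts$n_species / sum(counts$n_species),
                  counts$class)
}

#' @rdname filterConfig
#' @details \code{readFilterConfig} reads threshold overrides from a YAML
#'   key-value file (unknown keys and invalid values are rejected exactly
#'   as for \code{filterConfig}).
#' @param path path to a YAML file of named overrides.
#' @export
readFilterConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  overrides <- yaml::read_yaml(path)
  if (is.null(overrides)) return(filterConfig())
  do.call(filterConfig, overrides)
}
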