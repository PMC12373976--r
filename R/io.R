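# Readers/writers for the plain-text interchange formats used by every
# stage: counts TSV, AOI annotation TSV, negative-probe TSV, GMT gene
# sets, survival TSV, and a flat YAML/JSON config.

COMPARTMENTS <- c("EP", "MA", "ST")
GRADES <- c("well", "moderate", "poor")

#' Default pipeline configuration
#'
#' Flat list of every tunable threshold in the pipeline, with the
#' platform-convention defaults: technical QC (NTC > 1000, nuclei < 100,
#' alignment < 0.8 fail an AOI), a minimum negative-probe detection floor
#' of 4 counts, gene retention at >= 10% detection, DE screening at
#' |logFC| > 1 and p < .05, trend-pattern eligibility at p < .1 in at
#' least two pairwise comparisons, epithelial contamination score
#' threshold 0.05 on the rescaled [0,1] scale, ssGSEA rank-weight
#' exponent 0.25 with global-range score normalization, deconvolution
#' retention at permutation p < .05 and R > .7 with 1000 permutations and
#' quantile normalization, and Cox options (Breslow ties; a small L2
#' ridge of 0.1 in the pipeline config, since composite-signature genes
#' are strongly co-expressed and the unpenalized information matrix can
#' be near-singular at cohort-scale n).
#'
#' @return named list of configuration values
#' @export
default_config <- function() {
  list(
    ntc_max            = 1000,
    min_nuclei         = 100,
    min_alignment      = 0.8,
    negprobe_floor     = 4,
    min_detect_fraction = 0.1,
    lfc_thr            = 1.0,
    p_thr              = 0.05,
    pattern_p_thr      = 0.1,
    pattern_adjust     = FALSE,
    contamination_thr  = 0.05,
    contamination_mode = "fixed",
    ssgsea_alpha       = 0.25,
    ssgsea_normalize   = TRUE,
    deconv_n_perm      = 1000,
    deconv_qn          = TRUE,
    deconv_p_max       = 0.05,
    deconv_r_min       = 0.7,
    cox_ties           = "breslow",
    cox_ridge          = 0.1,
    cox_max_iter       = 50,
    cox_tol            = 1e-8,
    seed               = 1L
  )
}

#' Read (or merge) a pipeline configuration file
#'
#' Accepts a flat YAML or JSON document; keys present in the file
#' override the defaults, unknown keys are an error.
#'
#' @param path path to a YAML or JSON file, or NULL for pure defaults
#' @return validated configuration list
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0) {
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    }
    cfg[names(user)] <- user
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$ntc_max >= 0, cfg$min_nuclei >= 0,
    cfg$min_alignment >= 0, cfg$min_alignment <= 1,
    cfg$negprobe_floor >= 0,
    cfg$min_detect_fraction >= 0, cfg$min_detect_fraction <= 1,
    cfg$lfc_thr >= 0, cfg$p_thr > 0, cfg$p_thr <= 1,
    cfg$pattern_p_thr > 0, cfg$pattern_p_thr <= 1,
    cfg$contamination_thr >= 0, cfg$contamination_thr <= 1,
    cfg$ssgsea_alpha >= 0,
    cfg$deconv_n_perm >= 100,
    cfg$deconv_p_max > 0, cfg$deconv_p_max <= 1,
    cfg$deconv_r_min >= -1, cfg$deconv_r_min <= 1,
    cfg$cox_ridge >= 0
  )
  cfg$contamination_mode <- match.arg(cfg$contamination_mode,
                                      c("fixed", "data_driven"))
  cfg
}

#' Write a configuration list to YAML
#'
#' @param cfg configuration list
#' @param path output path
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(validate_config(cfg), path)
  invisible(path)
}

read_numeric_matrix <- function(path, what = "gene") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix file needs an id column plus >=1 AOI column")
  ids <- as.character(df[[1]])
  aoi_ids <- colnames(df)[-1]
  if (anyDuplicated(aoi_ids)) {
    stop("duplicate AOI id in header: ",
         paste(unique(aoi_ids[duplicated(aoi_ids)]), collapse = ", "))
  }
  raw <- as.matrix(df[, -1, drop = FALSE])
  m <- matrix(suppressWarnings(as.numeric(raw)), nrow = nrow(raw))
  if (anyNA(m)) {
    bad <- arrayInd(which(is.na(m))[1], dim(m))
    stop(sprintf("missing/non-numeric cell at %s row %s, column %s",
                 what, ids[bad[1, 1]], aoi_ids[bad[1, 2]]))
  }
  if (any(m < 0)) stop("negative counts are not allowed")
  rownames(m) <- NULL
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    pipeline_log("read_numeric_matrix: collapsing %d duplicate %s row(s) by sum (%s)",
                 length(dups), what, paste(utils::head(dups, 5), collapse = ", "))
    m <- rowsum(m, group = ids)
    ids <- rownames(m)
    warning("duplicate ", what, " rows collapsed by sum: ",
            paste(dups, collapse = ", "))
    # rowsum sorts groups; restore first-appearance order
    first_order <- unique(as.character(utils::read.delim(path, sep = "\t",
                            check.names = FALSE)[, 1]))
    m <- m[first_order, , drop = FALSE]
    ids <- first_order
  }
  rownames(m) <- ids
  colnames(m) <- aoi_ids
  m
}

#' Read a gene x AOI count matrix from TSV
#'
#' First column gene symbols, remaining columns one per AOI. Duplicate
#' gene rows are collapsed by summation with a warning; negative or
#' non-numeric cells are an error.
#'
#' @param path TSV file path
#' @return numeric matrix, genes in rows (rownames), AOIs in columns
#' @export
read_count_matrix <- function(path) {
  read_numeric_matrix(path, what = "gene")
}

#' Read a negative-probe x AOI count matrix from TSV
#'
#' @param path TSV file path
#' @return numeric matrix, probes in rows, AOIs in columns
#' @export
read_negprobe_matrix <- function(path) {
  read_numeric_matrix(path, what = "probe")
}

ANNOTATION_COLS <- c("aoi_id", "roi_id", "patient_id", "compartment",
                     "grade", "nuclei", "alignment_rate", "ntc_count")

#' Validate an AOI annotation table
#'
#' Checks the closed compartment/grade vocabularies, metric ranges and
#' aoi_id uniqueness. Used by both the reader and the simulator.
#'
#' @param ann data.frame with the annotation columns
#' @return the validated data.frame (order preserved)
#' @export
validate_annotations <- function(ann) {
  missing <- setdiff(ANNOTATION_COLS, colnames(ann))
  if (length(missing) > 0) {
    stop("annotation table missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(ann$aoi_id)) stop("duplicate aoi_id in annotations")
  bad <- setdiff(unique(ann$compartment), COMPARTMENTS)
  if (length(bad) > 0) {
    stop("unknown compartment token(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(COMPARTMENTS, collapse = ", "))
  }
  bad <- setdiff(unique(ann$grade), c(GRADES, "unknown"))
  if (length(bad) > 0) {
    stop("unknown grade token(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(c(GRADES, "unknown"), collapse = ", "))
  }
  # range checks tolerate NA so that technical_qc can name the AOI
  stopifnot(all(ann$nuclei >= 0, na.rm = TRUE),
            all(ann$ntc_count >= 0, na.rm = TRUE),
            all(ann$alignment_rate >= 0 & ann$alignment_rate <= 1,
                na.rm = TRUE))
  ann
}

#' Read an AOI annotation TSV
#'
#' Required columns: aoi_id, roi_id, patient_id, compartment (EP/MA/ST),
#' grade (well/moderate/poor/unknown), nuclei, alignment_rate, ntc_count.
#'
#' @param path TSV file path
#' @return validated annotation data.frame
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  for (col in intersect(c("aoi_id", "roi_id", "patient_id"), colnames(ann))) {
    ann[[col]] <- as.character(ann[[col]])
  }
  validate_annotations(ann)
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: set name, description, then one gene symbol per
#' field. Empty member lists and duplicate set names are errors.
#'
#' @param path GMT file path
#' @return named list of character vectors; set descriptions in
#'   `attr(, "description")`
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names_)) {
    stop("duplicate gene set name: ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) {
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (length(f) < 3 || length(members) == 0) {
      stop("gene set '", f[[1]], "' has no members")
    }
    unique(members)
  })
  names(sets) <- names_
  attr(sets, "description") <- stats::setNames(
    vapply(fields, function(f) if (length(f) >= 2) f[[2]] else "", ""), names_)
  sets
}

#' Write gene sets to GMT
#'
#' @param sets named list of character vectors
#' @param path output path
#' @param descriptions optional character vector of descriptions
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, members) {
    paste(c(nm, desc, members), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a patient survival TSV
#'
#' Columns: patient_id, time (months, >= 0), event (0/1).
#'
#' @param path TSV file path
#' @return validated data.frame, one row per patient
#' @export
read_survival <- function(path) {
  surv <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  missing <- setdiff(c("patient_id", "time", "event"), colnames(surv))
  if (length(missing) > 0) {
    stop("survival table missing columns: ", paste(missing, collapse = ", "))
  }
  surv$patient_id <- as.character(surv$patient_id)
  if (anyDuplicated(surv$patient_id)) stop("duplicate patient_id")
  stopifnot(all(surv$time >= 0), all(surv$event %in% c(0, 1)))
  surv
}

#' Write a stage output as a deterministic TSV
#'
#' Rows sorted by the first (primary key) column, floats at 6
#' significant digits, tab separation with a header.
#'
#' @param records data.frame
#' @param path output path
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (nrow(records) > 0) {
    records <- records[order(records[[1]]), , drop = FALSE]
    for (j in seq_along(records)) {
      if (is.double(records[[j]])) {
        records[[j]] <- signif(records[[j]], 6)
      }
    }
  }
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a count matrix as TSV (genes in rows)
#'
#' @param m numeric matrix with rownames (genes) and colnames (AOIs)
#' @param path output path
#' @param id_col name for the identifier column
#' @export
write_matrix <- function(m, path, id_col = "gene") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
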