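# Data model and I/O: intensity matrices, peptide annotations, clinical
# tables, clinical dichotomizations, log transformation and annotation-based
# abundance aggregation. All downstream stages consume these containers.


#' Validate a peptide intensity matrix
#'
#' An intensity matrix is a numeric matrix with samples in rows and peptide
#' features in columns. Values are nonnegative label-free abundances; zero
#' means the peptide was not detected in that sample.
#'
#' @param m numeric matrix with unique row (sample) and column (feature) names.
#' @return `m`, invisibly, after validation.
#' @export
validate_intensity_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    abort_fmt("intensity data must be a numeric matrix")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort_fmt("intensity matrix needs sample row names and feature column names")
  }
  if (anyDuplicated(rownames(m))) {
    abort_fmt("duplicated sample id: %s",
              paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(m))) {
    abort_fmt("duplicated feature id: %s",
              paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  if (anyNA(m)) abort_fmt("intensity matrix contains missing values")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    abort_fmt("negative intensity at sample '%s', feature '%s'",
              rownames(m)[bad[1L]], colnames(m)[bad[2L]])
  }
  invisible(m)
}

#' Read a peptide intensity table
#'
#' Reads a delimited samples-by-features table (TSV by default, header row of
#' feature ids, first column of sample ids). Missing cells are treated as
#' "not detected" (0) and counted in the load report attached as attribute
#' `"load_report"`. Negative or non-numeric cells and duplicated ids are hard
#' errors.
#'
#' @param path file path.
#' @param sep field separator, tab by default.
#' @param transpose set `TRUE` when the file stores features in rows.
#' @return validated intensity matrix (samples x features).
#' @export
read_intensity_matrix <- function(path, sep = "\t", transpose = FALSE) {
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (ncol(raw) < 2L) abort_fmt("'%s': expected an id column plus data columns", path)
  header <- colnames(raw)[-1L]   # before subsetting, which uniquifies names
  if (anyDuplicated(header)) {
    abort_fmt("duplicated feature id: %s",
              paste(unique(header[duplicated(header)]), collapse = ", "))
  }
  ids <- as.character(raw[[1L]])
  dat <- raw[, -1L, drop = FALSE]
  for (j in seq_along(dat)) {
    col <- dat[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(!is.na(col) & col != "" & is.na(num))
      if (length(bad)) {
        abort_fmt("non-numeric value '%s' at row '%s', column '%s'",
                  col[bad[1L]], ids[bad[1L]], colnames(dat)[j])
      }
      dat[[j]] <- num
    }
  }
  m <- as.matrix(dat)
  n_missing <- sum(is.na(m))
  m[is.na(m)] <- 0
  rownames(m) <- ids
  if (transpose) m <- t(m)
  validate_intensity_matrix(m)
  attr(m, "load_report") <- list(path = path, n_missing_as_zero = n_missing)
  m
}

#' Write a peptide intensity table
#'
#' Inverse of [read_intensity_matrix()]: TSV, header row of feature ids,
#' first column `sample_id`.
#'
#' @param m validated intensity matrix.
#' @param path output path.
#' @export
write_intensity_matrix <- function(m, path) {
  validate_intensity_matrix(m)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a peptide annotation table
#'
#' Each peptide feature carries an origin class (`"microbial"` or `"human"`),
#' a seven-rank taxonomic lineage (superkingdom to species) that may be
#' truncated from the bottom — produced upstream by lowest-common-ancestor
#' assignment — and an optional functional code (`Kxxxxx` KEGG orthologous
#' group or custom `CKO-` code). Human peptides carry no lineage.
#'
#' @param ann data frame with columns `feature_id`, `origin`, the seven rank
#'   columns, and `function_code` (NA when absent).
#' @return `ann`, invisibly, after validation.
#' @export
validate_annotation_table <- function(ann) {
  needed <- c("feature_id", "origin", TAXONOMIC_RANKS, "function_code")
  missing <- setdiff(needed, names(ann))
  if (length(missing)) abort_fmt("annotation table lacks column(s): %s",
                                 paste(missing, collapse = ", "))
  if (anyDuplicated(ann$feature_id)) {
    abort_fmt("duplicated feature id in annotations: %s",
              ann$feature_id[duplicated(ann$feature_id)][1L])
  }
  if (!all(ann$origin %in% c("microbial", "human"))) {
    abort_fmt("origin must be 'microbial' or 'human'")
  }
  lin <- as.matrix(ann[, TAXONOMIC_RANKS])
  lin[lin == ""] <- NA
  # lineage must be a prefix of a full path: no taxon below a missing rank
  present <- !is.na(lin)
  if (nrow(lin)) {
    ok <- apply(present, 1L, function(p) all(diff(as.integer(p)) <= 0L) ||
                  !any(p))
    # prefix property: once a rank is missing, all deeper ranks are missing,
    # i.e. the presence indicator is nonincreasing along the ladder
    if (!all(ok)) {
      abort_fmt("lineage of '%s' has a gap (taxon below a missing rank)",
                ann$feature_id[which(!ok)[1L]])
    }
  }
  human <- ann$origin == "human"
  if (any(human & rowSums(present) > 0L)) {
    abort_fmt("human feature '%s' carries a taxonomic lineage",
              ann$feature_id[which(human & rowSums(present) > 0L)[1L]])
  }
  fc <- ann$function_code
  has_fc <- !is.na(fc) & fc != ""
  bad_fc <- has_fc & !grepl("^K[0-9]{5}$|^CKO-", fc)
  if (any(bad_fc)) abort_fmt("malformed function code '%s'", fc[which(bad_fc)[1L]])
  invisible(ann)
}

#' Read / write a peptide annotation table (TSV)
#'
#' @param path file path.
#' @return validated annotation data frame.
#' @export
read_annotation_table <- function(path) {
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", na.strings = c("NA", ""))
  ann$feature_id <- as.character(ann$feature_id)
  validate_annotation_table(ann)
  ann
}

#' @rdname read_annotation_table
#' @param ann annotation data frame.
#' @export
write_annotation_table <- function(ann, path) {
  validate_annotation_table(ann)
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Validate a clinical metadata table
#'
#' One row per patient sample: gender (`M`/`F`), age in years, tumor site
#' (`right colon`/`left colon`), AJCC stage (`I`-`IV`), grade (`G1`-`G3`) and
#' tumor-infiltrating lymphocyte percentage (`tils`, 0-100). Rows with any
#' missing field are rejected — the pipeline mirrors the exclusion of cases
#' with incomplete clinicopathological information.
#'
#' @param clinical data frame with columns `sample_id`, `gender`, `age`,
#'   `site`, `stage`, `grade`, `tils`.
#' @return `clinical`, invisibly, after validation.
#' @export
validate_clinical_table <- function(clinical) {
  missing <- setdiff(CLINICAL_COLUMNS, names(clinical))
  if (length(missing)) abort_fmt("clinical table lacks column(s): %s",
                                 paste(missing, collapse = ", "))
  if (anyDuplicated(clinical$sample_id)) {
    abort_fmt("duplicated sample id in clinical table: %s",
              clinical$sample_id[duplicated(clinical$sample_id)][1L])
  }
  if (anyNA(clinical[, CLINICAL_COLUMNS])) {
    bad <- which(rowSums(is.na(clinical[, CLINICAL_COLUMNS])) > 0L)[1L]
    abort_fmt("incomplete clinical row for sample '%s'", clinical$sample_id[bad])
  }
  checks <- list(
    gender = clinical$gender %in% c("M", "F"),
    site   = clinical$site %in% c("right colon", "left colon"),
    stage  = clinical$stage %in% c("I", "II", "III", "IV"),
    grade  = clinical$grade %in% c("G1", "G2", "G3"),
    age    = is.numeric(clinical$age) & clinical$age > 0,
    tils   = is.numeric(clinical$tils) & clinical$tils >= 0 & clinical$tils <= 100
  )
  for (nm in names(checks)) {
    if (!all(checks[[nm]])) {
      abort_fmt("invalid %s for sample '%s'", nm,
                clinical$sample_id[which(!checks[[nm]])[1L]])
    }
  }
  invisible(clinical)
}

# map loose header spellings (e.g. "Sample code", "TILs (%)") onto canonical names
normalize_clinical_names <- function(nms) {
  key <- gsub("[^a-z]", "", tolower(nms))
  canon <- c(samplecode = "sample_id", sampleid = "sample_id", sample = "sample_id",
             gender = "gender", sex = "gender",
             ageatdiagnosis = "age", age = "age",
             site = "site", stage = "stage", grade = "grade",
             tils = "tils")
  out <- canon[key]
  ifelse(is.na(out), nms, out)
}

#' Read a clinical metadata table (CSV)
#'
#' Accepts canonical column names (`sample_id`, `gender`, `age`, `site`,
#' `stage`, `grade`, `tils`) as well as the header style of clinical report
#' tables ("Sample code", "Age at diagnosis", "TILs (%)", ...).
#'
#' @param path CSV file path.
#' @return validated clinical data frame.
#' @export
read_clinical_table <- function(path) {
  clinical <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(clinical) <- normalize_clinical_names(names(clinical))
  clinical$sample_id <- as.character(clinical$sample_id)
  validate_clinical_table(clinical)
  clinical[, CLINICAL_COLUMNS]
}

#' The bundled 24-patient colon cancer cohort
#'
#' Clinical characteristics of an example cohort of 24 colon cancer patients
#' (gender, age at diagnosis, tumor site, AJCC stage, grade, TILs percent)
#' shipped with the package as a plain CSV. It drives the worked examples and
#' the acceptance checks of the clinical-grouping operations.
#'
#' @return validated clinical data frame with 24 rows.
#' @export
reference_cohort <- function() {
  path <- system.file("extdata", "colon_cohort.csv", package = "lumiprot",
                      mustWork = TRUE)
  read_clinical_table(path)
}

#' Define a two-group clinical comparison
#'
#' The three tumor dichotomizations used throughout the pipeline:
#' * `stage`: stage I-II (group A) vs. stage III-IV (group B);
#' * `grade`: G1-G2 (A) vs. G3 (B);
#' * `tils`: TILs-positive, >= 5% (A) vs. TILs-negative, exactly 0% (B).
#'   TILs values strictly between 0 and 5 are not covered by the rule and
#'   are rejected by [assign_groups()] rather than silently binned.
#'
#' @param variable one of `"stage"`, `"grade"`, `"tils"`.
#' @return a `comparison_spec` object.
#' @export
comparison_spec <- function(variable = c("stage", "grade", "tils")) {
  variable <- match.arg(variable)
  labels <- switch(variable,
    stage = c(A = "Stage I-II", B = "Stage III-IV"),
    grade = c(A = "G1-2",       B = "G3"),
    tils  = c(A = "TILs+",      B = "TILs-"))
  structure(list(variable = variable, group_labels = labels),
            class = "comparison_spec")
}

#' @export
print.comparison_spec <- function(x, ...) {
  cat(sprintf("comparison on %s: A = %s, B = %s\n", x$variable,
              x$group_labels[["A"]], x$group_labels[["B"]]))
  invisible(x)
}

#' Assign samples to the two groups of a clinical comparison
#'
#' @param clinical validated clinical table.
#' @param spec a [comparison_spec()].
#' @return factor of `"A"`/`"B"` named by sample id, with attributes
#'   `group_sizes` (named counts) and `group_labels`.
#' @export
assign_groups <- function(clinical, spec) {
  validate_clinical_table(clinical)
  stopifnot(inherits(spec, "comparison_spec"))
  g <- switch(spec$variable,
    stage = ifelse(clinical$stage %in% c("I", "II"), "A", "B"),
    grade = ifelse(clinical$grade %in% c("G1", "G2"), "A", "B"),
    tils = {
      t <- clinical$tils
      undef <- t > 0 & t < 5
      if (any(undef)) {
        abort_fmt(paste0("TILs value %s%% for sample '%s' is strictly between ",
                         "0 and 5 and undefined under the TILs+/TILs- rule"),
                  t[which(undef)[1L]], clinical$sample_id[which(undef)[1L]])
      }
      ifelse(t >= 5, "A", "B")
    })
  g <- factor(g, levels = c("A", "B"))
  names(g) <- clinical$sample_id
  attr(g, "group_sizes") <- c(A = sum(g == "A"), B = sum(g == "B"))
  attr(g, "group_labels") <- spec$group_labels
  g
}

#' Log-transform peptide intensities
#'
#' `value -> log(value + pseudocount, base)`; base 2 with pseudocount 1 by
#' default so a not-detected peptide maps to 0 and injected effects live on
#' the log2 fold-change scale used by the power module.
#'
#' @param m intensity matrix.
#' @param pseudocount positive offset added before taking logs.
#' @param base logarithm base.
#' @return transformed matrix (same dimnames).
#' @export
log_transform <- function(m, pseudocount = 1, base = 2) {
  validate_intensity_matrix(m)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0) {
    abort_fmt("`pseudocount` must be a single positive number")
  }
  log(m + pseudocount, base = base)
}

#' Total-sum scale an intensity matrix (optional normalization)
#'
#' Divides each sample row by its total so rows sum to 1. Not applied by
#' default anywhere in the pipeline; provided as an opt-in normalization.
#'
#' @param m intensity matrix.
#' @return row-normalized matrix; all-zero rows are left at zero.
#' @export
total_sum_scale <- function(m) {
  validate_intensity_matrix(m)
  tot <- rowSums(m)
  tot[tot == 0] <- 1
  m / tot
}

#' Aggregate peptide intensities by annotation
#'
#' The abundance of a taxonomic or functional category is the sum of the
#' intensities of all peptides annotated with that category. Peptides with no
#' annotation at the requested level fall into an explicit `"unassigned"`
#' bucket, so per-sample totals are conserved exactly.
#'
#' @param m intensity matrix (samples x peptides).
#' @param ann validated annotation table covering the features of `m`.
#' @param level one of the seven taxonomic ranks or `"function"`.
#' @return samples x categories matrix with attribute `level`.
#' @export
aggregate_by_annotation <- function(m, ann, level) {
  validate_intensity_matrix(m)
  validate_annotation_table(ann)
  if (!(level %in% c(TAXONOMIC_RANKS, "function"))) {
    abort_fmt("unknown aggregation level '%s'", level)
  }
  missing <- setdiff(colnames(m), ann$feature_id)
  if (length(missing)) {
    abort_fmt("feature '%s' absent from the annotation table", missing[1L])
  }
  key <- if (level == "function") "function_code" else level
  cat <- ann[[key]][match(colnames(m), ann$feature_id)]
  cat[is.na(cat) | cat == ""] <- "unassigned"
  agg <- t(rowsum(t(m), group = cat))
  agg <- agg[, order(colnames(agg)), drop = FALSE]
  validate_intensity_matrix(agg)
  attr(agg, "level") <- level
  agg
}

#' Map each feature to its category at one annotation level
#'
#' @param ann validated annotation table.
#' @param level a taxonomic rank or `"function"`.
#' @return character vector named by feature id; `NA` when unannotated.
#' @export
feature_categories <- function(ann, level) {
  validate_annotation_table(ann)
  if (!(level %in% c(TAXONOMIC_RANKS, "function"))) {
    abort_fmt("unknown annotation level '%s'", level)
  }
  key <- if (level == "function") "function_code" else level
  out <- ann[[key]]
  out[out == ""] <- NA
  names(out) <- ann$feature_id
  out
}
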