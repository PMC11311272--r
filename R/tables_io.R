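# Domain containers and TSV/Bracken I/O.
#
# Three validated containers move through the pipeline:
#   count_table       samples x species integer read counts
#   sample_metadata   per-sample group / matched-cohort / sex / age / timepoint
#   metabolite_table  samples x 16 fecal metabolite concentrations (ug per g)

#' Recognised sample groups
#'
#' Seven malignancy groups plus healthy controls (`HC`).
#'
#' @return Character vector of valid `group` labels.
#' @export
cancer_groups <- function() {
  c("CRC", "stomach", "breast", "lung", "melanoma", "lymphoid", "AML", "HC")
}

#' The fixed fecal metabolite panel
#'
#' Seven short-chain fatty acids and nine amino acids, in the canonical
#' column order used by every metabolite table in the package.
#'
#' @return Character vector of 16 metabolite names.
#' @export
metabolite_names <- function() {
  c("acetic", "butanoic", "formic", "hexanoic", "isobutyric", "pentanoic",
    "propanoic",
    "Ala", "Gly", "Glu", "Ile", "Leu", "Met", "Phe", "Pro", "Val")
}

#' Construct a validated species count table
#'
#' @param counts Non-negative integer matrix, samples in rows, species in
#'   columns; dimnames supply identifiers unless given explicitly.
#' @param sample_ids,species_names Optional identifier vectors overriding
#'   the matrix dimnames.
#' @return An object of class `count_table`: a list with elements
#'   `counts`, `sample_ids`, `species_names` and `total_reads`.
#' @export
count_table <- function(counts, sample_ids = rownames(counts),
                        species_names = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(species_names)) {
    stop("count_table needs sample and species identifiers (dimnames)")
  }
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', species '%s'",
                 sample_ids[bad[1]], species_names[bad[2]]))
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integers (read counts)")
  }
  counts <- round(counts)
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  if (anyDuplicated(species_names)) stop("duplicate species names")
  dimnames(counts) <- list(sample_ids, species_names)
  total <- rowSums(counts)
  if (any(total == 0)) {
    stop("samples with zero total reads: ",
         paste(sample_ids[total == 0], collapse = ", "))
  }
  structure(list(counts = counts,
                 sample_ids = as.character(sample_ids),
                 species_names = as.character(species_names),
                 total_reads = total),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d species, median depth %s reads\n",
              length(x$sample_ids), length(x$species_names),
              format(stats::median(x$total_reads), big.mark = ",")))
  invisible(x)
}

#' Per-sample relative abundances
#'
#' @param x A `count_table`.
#' @return Numeric matrix of counts divided by per-sample total reads;
#'   each row sums to 1.
#' @export
relative_abundance <- function(x) {
  stopifnot(inherits(x, "count_table"))
  x$counts / x$total_reads
}

#' Subset a count table by sample identifiers
#'
#' @param x A `count_table`.
#' @param sample_ids Identifiers to keep, in the order given.
#' @return A `count_table` restricted to those samples.
#' @export
subset_samples <- function(x, sample_ids) {
  stopifnot(inherits(x, "count_table"))
  missing <- setdiff(sample_ids, x$sample_ids)
  if (length(missing)) {
    stop("unknown sample identifiers: ", paste(missing, collapse = ", "))
  }
  count_table(x$counts[sample_ids, , drop = FALSE])
}

#' Construct validated sample metadata
#'
#' @param df Data frame with columns `sample_id`, `group`, `cohort`, `sex`,
#'   `age` and optionally `timepoint` (default `"pre"`).
#' @return A `sample_metadata` data frame.
#' @export
sample_metadata <- function(df) {
  req <- c("sample_id", "group", "cohort", "sex", "age")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (!"timepoint" %in% names(df)) df$timepoint <- "pre"
  df <- as.data.frame(df[c(req, "timepoint")], stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  bad_group <- setdiff(unique(df$group), cancer_groups())
  if (length(bad_group)) {
    stop("unknown group value(s): ", paste(bad_group, collapse = ", "))
  }
  bad_sex <- setdiff(unique(df$sex), c("F", "M"))
  if (length(bad_sex)) stop("unknown sex value(s): ", paste(bad_sex, collapse = ", "))
  bad_tp <- setdiff(unique(df$timepoint), c("pre", "post"))
  if (length(bad_tp)) stop("unknown timepoint value(s): ", paste(bad_tp, collapse = ", "))
  if (anyNA(df$age) || any(df$age <= 0)) stop("age must be positive")
  for (ch in unique(df$cohort[df$group != "HC"])) {
    if (!any(df$group == "HC" & df$cohort == ch)) {
      stop(sprintf("case cohort '%s' has no healthy-control samples", ch))
    }
  }
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Construct a validated metabolite concentration table
#'
#' Concentrations are per gram of stool. Missing values are allowed and
#' kept as `NA` (never silently zeroed); downstream modes decide how to
#' treat them.
#'
#' @param concentrations Numeric matrix, samples in rows; columns must be
#'   exactly the 16 names of [metabolite_names()] (any order accepted,
#'   stored in canonical order).
#' @param sample_ids Optional identifiers overriding rownames.
#' @return An object of class `metabolite_table`.
#' @export
metabolite_table <- function(concentrations, sample_ids = rownames(concentrations)) {
  concentrations <- as.matrix(concentrations)
  if (is.null(sample_ids)) stop("metabolite_table needs sample identifiers")
  want <- metabolite_names()
  miss <- setdiff(want, colnames(concentrations))
  if (length(miss)) {
    stop("missing metabolite column(s): ", paste(miss, collapse = ", "))
  }
  extra <- setdiff(colnames(concentrations), want)
  if (length(extra)) {
    stop("unknown metabolite column(s): ", paste(extra, collapse = ", "))
  }
  concentrations <- concentrations[, want, drop = FALSE]
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  if (any(concentrations < 0, na.rm = TRUE)) stop("concentrations must be >= 0")
  rownames(concentrations) <- sample_ids
  structure(list(concentrations = concentrations,
                 sample_ids = as.character(sample_ids),
                 metabolite_names = want),
            class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("metabolite_table: %d samples x %d metabolites (%d missing values)\n",
              length(x$sample_ids), length(x$metabolite_names),
              sum(is.na(x$concentrations))))
  invisible(x)
}

# ---- Bracken ----------------------------------------------------------------

.bracken_cols <- c("name", "taxonomy_id", "taxonomy_lvl", "kraken_assigned_reads",
                   "added_reads", "new_est_reads", "fraction_total_reads")

#' Merge per-sample Bracken species reports into a count table
#'
#' Reads one Bracken species-level report per sample and merges them over
#' the union of species names. Counts are taken from the `new_est_reads`
#' column (Bracken's re-estimated species counts); species absent from a
#' report get zero. Rows whose `taxonomy_lvl` is not `"S"` are skipped
#' with a warning.
#'
#' @param paths Character vector of report file paths, one per sample.
#' @param sample_ids Identifiers for the samples, same length as `paths`;
#'   defaults to the file base names.
#' @return A `count_table` with one row per report.
#' @export
read_bracken_reports <- function(paths,
                                 sample_ids = sub("\\.[^.]*$", "", basename(paths))) {
  stopifnot(length(paths) >= 1, length(sample_ids) == length(paths))
  per_file <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    df <- utils::read.delim(paths[i], header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    miss <- setdiff(.bracken_cols, names(df))
    if (length(miss)) {
      stop(sprintf("Bracken report '%s' is missing column(s): %s",
                   paths[i], paste(miss, collapse = ", ")))
    }
    not_species <- df$taxonomy_lvl != "S"
    if (any(not_species)) {
      warning(sprintf("'%s': skipped %d non-species row(s) (taxonomy_lvl != 'S')",
                      paths[i], sum(not_species)))
      df <- df[!not_species, , drop = FALSE]
    }
    if (anyDuplicated(df$name)) {
      stop(sprintf("Bracken report '%s' has duplicated species names", paths[i]))
    }
    per_file[[i]] <- stats::setNames(df$new_est_reads, df$name)
  }
  species <- sort(unique(unlist(lapply(per_file, names))))
  counts <- matrix(0L, nrow = length(paths), ncol = length(species),
                   dimnames = list(sample_ids, species))
  for (i in seq_along(per_file)) {
    counts[i, names(per_file[[i]])] <- per_file[[i]]
  }
  count_table(counts)
}

# ---- plain TSV --------------------------------------------------------------

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

.write_tsv <- function(df, path, label = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- sprintf("# gmci %s", as.character(utils::packageVersion("gmci")))
  if (!is.null(label)) hdr <- paste(hdr, label)
  if (!is.null(seed)) hdr <- paste0(hdr, " seed=", seed)
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a plain TSV count matrix
#'
#' @param path TSV file with a header row and a leading label column.
#' @param orientation `"samples_in_rows"` (default) or `"species_in_rows"`.
#' @return A `count_table`, always samples x species.
#' @export
read_count_matrix <- function(path,
                              orientation = c("samples_in_rows", "species_in_rows")) {
  orientation <- match.arg(orientation)
  df <- .read_tsv(path)
  if (ncol(df) < 2) stop("count matrix needs a label column plus data columns")
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    suppressWarnings(num <- as.numeric(m[, j]))
    bad <- which(is.na(num) & !is.na(m[, j]))
    if (length(bad)) {
      stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                   labels[bad[1]], colnames(m)[j], path))
    }
    if (any(num < 0, na.rm = TRUE)) {
      bad <- which(num < 0)[1]
      stop(sprintf("negative cell at row '%s', column '%s' in %s",
                   labels[bad], colnames(m)[j], path))
    }
  }
  storage.mode(m) <- "numeric"
  rownames(m) <- labels
  if (orientation == "species_in_rows") m <- t(m)
  count_table(m)
}

#' Write a count table as TSV
#'
#' Writes samples in rows with a `sample_id` label column and a `#` header
#' comment recording the package version (and seed, if given) for audit.
#'
#' @param x A `count_table`.
#' @param path Output file.
#' @param seed Optional integer recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "count_table"))
  df <- data.frame(sample_id = x$sample_ids, x$counts, check.names = FALSE)
  .write_tsv(df, path, "count_matrix", seed)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' @param path TSV with columns `sample_id`, `group`, `cohort`, `sex`,
#'   `age` and optionally `timepoint`.
#' @return A `sample_metadata` data frame.
#' @export
read_metadata <- function(path) {
  sample_metadata(.read_tsv(path))
}

#' Write sample metadata as TSV
#'
#' @inheritParams write_count_matrix
#' @param x A `sample_metadata` data frame.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "sample_metadata"))
  .write_tsv(as.data.frame(x), path, "metadata", seed)
  invisible(path)
}

#' Read a metabolite concentration table from TSV
#'
#' @param path TSV with a `sample_id` column plus the 16 fixed metabolite
#'   columns of [metabolite_names()].
#' @return A `metabolite_table`.
#' @export
read_metabolites <- function(path) {
  df <- .read_tsv(path)
  if (!"sample_id" %in% names(df)) stop("metabolite table needs a sample_id column")
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- as.character(df$sample_id)
  metabolite_table(m)
}

#' Write a metabolite table as TSV
#'
#' @inheritParams write_count_matrix
#' @param x A `metabolite_table`.
#' @return `path`, invisibly.
#' @export
write_metabolites <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "metabolite_table"))
  df <- data.frame(sample_id = x$sample_ids, x$concentrations, check.names = FALSE)
  .write_tsv(df, path, "metabolites", seed)
  invisible(path)
}

#' Check that every counted sample has metadata
#'
#' @param x A `count_table`.
#' @param meta A `sample_metadata` data frame.
#' @return Invisibly `TRUE`; errors listing identifiers otherwise.
#' @export
reconcile_samples <- function(x, meta) {
  stopifnot(inherits(x, "count_table"), inherits(meta, "sample_metadata"))
  missing <- setdiff(x$sample_ids, meta$sample_id)
  if (length(missing)) {
    stop("samples present in counts but absent from metadata: ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

# Resolve one cohort comparison into case and control sample id sets.
.cohort_samples <- function(meta, cohort, timepoint = "pre") {
  stopifnot(inherits(meta, "sample_metadata"))
  sel <- meta$cohort == cohort & meta$timepoint == timepoint
  if (!any(sel)) stop(sprintf("no samples for cohort '%s'", cohort))
  cases <- meta$sample_id[sel & meta$group != "HC"]
  controls <- meta$sample_id[sel & meta$group == "HC"]
  if (length(cases) == 0) stop(sprintf("cohort '%s' has no case samples", cohort))
  if (length(controls) == 0) stop(sprintf("cohort '%s' has no control samples", cohort))
  list(cases = cases, controls = controls)
}
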