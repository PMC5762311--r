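#' Read a gene-by-sample expression matrix
#'
#' Reads a tab-delimited matrix with gene symbols in the first column and a
#' header row of sample identifiers. Values are assumed to be on the log2
#' scale. Duplicate gene rows (multiple probes mapping to one symbol) are
#' collapsed by averaging; symbols are uppercased.
#'
#' @param path Path to a tab-delimited text file.
#' @param sep Field separator (default tab).
#' @return A numeric matrix (genes x samples) with a `standardized` attribute
#'   set to `FALSE`.
#' @seealso [standardize_genes()], [write_expression()]
#' @export
read_expression <- function(path, sep = "\t") {
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("empty matrix: no data rows/sample columns in ", path)
  }
  genes <- toupper(as.character(raw[[1L]]))
  body <- raw[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))) &
                     !is.na(body[[j]]))[1L]
      stop("non-numeric value in column '", names(body)[j],
           "', row ", if (is.na(bad)) "?" else bad,
           " (gene ", if (is.na(bad)) "?" else genes[bad], ")")
    }
  }
  m <- as.matrix(body)
  if (anyDuplicated(genes)) {
    m <- rowsum(m, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    rownames(m) <- unique(genes)
  } else {
    rownames(m) <- genes
  }
  if (anyDuplicated(colnames(m))) stop("duplicate sample IDs in header")
  if (anyNA(m) || any(!is.finite(m))) {
    stop("missing or non-finite expression values are not supported")
  }
  attr(m, "standardized") <- FALSE
  m
}

#' Write an expression matrix
#'
#' @param m Numeric matrix, genes x samples.
#' @param path Output path (tab-delimited, first column `gene`).
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene-wise standardization within a cohort
#'
#' Transforms every gene row to zero mean and unit standard deviation
#' (denominator n-1) across the cohort's samples. Constant rows are set to
#' zero rather than dropped, so matrix shapes stay stable; they contribute
#' nothing to correlation screens or compound scores. Expression must be
#' standardized per cohort before signatures are applied across platforms.
#'
#' @param m Numeric matrix, genes x samples.
#' @param force Re-standardize even if the matrix is already flagged
#'   standardized (a no-op up to numerical noise).
#' @return The standardized matrix with attribute `standardized = TRUE`.
#' @export
standardize_genes <- function(m, force = FALSE) {
  if (isTRUE(attr(m, "standardized")) && !force) {
    stop("matrix is already standardized (use force = TRUE to redo)")
  }
  if (ncol(m) < 2L) stop("cannot standardize a single-sample cohort (SD undefined)")
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  out <- (m - mu) / ifelse(sdv > 0, sdv, 1)
  out[sdv == 0, ] <- 0
  attr(out, "standardized") <- TRUE
  out
}

is_standardized <- function(m) isTRUE(attr(m, "standardized"))

#' Read a gene-level thresholded GISTIC copy-number table
#'
#' Accepts the GISTIC `all_thresholded.by_genes` dialect: columns named
#' `Locus ID` / `Cytoband` (or close variants) are dropped; remaining columns
#' are samples. Entries must be the five thresholded levels -2..2.
#'
#' @param path Tab-delimited file, genes in rows.
#' @return Integer matrix (genes x samples) with entries in -2..2.
#' @export
read_gistic <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty copy-number table")
  drop <- grepl("^(locus[ ._]?id|cytoband)$", tolower(names(raw)))
  drop[1L] <- FALSE
  raw <- raw[, !drop, drop = FALSE]
  genes <- toupper(as.character(raw[[1L]]))
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m %in% -2L:2L)) {
    stop("copy-number entries must be thresholded GISTIC levels -2..2")
  }
  rownames(m) <- genes
  m
}

#' Build a binary mutation matrix from a MAF-like table
#'
#' One row per mutation with at least `Hugo_Symbol`, `Tumor_Sample_Barcode`
#' and `Variant_Classification` columns. Classes listed in `silent` do not
#' count as mutations; everything else marks the gene mutated in that sample.
#'
#' @param path Tab-delimited MAF-like file.
#' @param silent Variant classes excluded as non-somatic-coding.
#' @param samples Optional full sample universe (columns of the output);
#'   defaults to the samples seen in the file.
#' @return Binary integer matrix, genes x samples.
#' @export
read_maf <- function(path,
                     silent = c("Silent", "Intron", "3'UTR", "5'UTR", "IGR", "RNA"),
                     samples = NULL) {
  maf <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(need, names(maf))
  if (length(miss)) stop("MAF file missing columns: ", paste(miss, collapse = ", "))
  maf <- maf[!(maf$Variant_Classification %in% silent), , drop = FALSE]
  genes <- sort(unique(toupper(maf$Hugo_Symbol)))
  if (is.null(samples)) samples <- sort(unique(maf$Tumor_Sample_Barcode))
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  keep <- maf$Tumor_Sample_Barcode %in% samples
  m[cbind(match(toupper(maf$Hugo_Symbol[keep]), genes),
          match(maf$Tumor_Sample_Barcode[keep], samples))] <- 1L
  m
}

#' Read a clinical table
#'
#' Tab-delimited with a `sample_id` column; recognised columns include
#' `os_time` (months), `os_event` (0/1), `dfs_time`, `dfs_event`,
#' `hpv_status` (positive/negative/unknown), `sex`, `age`, `anatomic_site`,
#' `t_stage`, `n_stage`, `overall_stage`, `radiation` (yes/no/unknown),
#' `cohort_name`. Unknowns are encoded `NA`.
#'
#' @param path Tab-delimited file.
#' @return A data.frame keyed by `sample_id`.
#' @export
read_clinical <- function(path) {
  cl <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"sample_id" %in% names(cl)) stop("clinical table must have a sample_id column")
  if (anyDuplicated(cl$sample_id)) stop("duplicate sample_id in clinical table")
  for (v in c("os_time", "dfs_time")) {
    if (v %in% names(cl) && any(cl[[v]] < 0, na.rm = TRUE)) {
      stop("negative survival times in ", v)
    }
  }
  for (v in c("os_event", "dfs_event")) {
    if (v %in% names(cl) && !all(cl[[v]] %in% c(0, 1, NA))) {
      stop("event flags must be 0/1 in ", v)
    }
  }
  cl
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then gene symbols, tab-separated.
#'
#' @param path GMT file path.
#' @return `read_gmt()`: named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    toupper(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1L]][1L], "")
  out
}

#' @rdname read_gmt
#' @param sets Named list of character vectors (gene symbols), or a single
#'   character vector with `name`.
#' @param name Set name when `sets` is a plain vector.
#' @param description Description field (second GMT column).
#' @export
write_gmt <- function(sets, path, name = "gene_set", description = "na") {
  if (!is.list(sets)) sets <- stats::setNames(list(sets), name)
  if (any(!lengths(sets))) stop("gene sets must be non-empty")
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, toupper(sets[[nm]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Truncate sample barcodes to a patient-level prefix
#'
#' TCGA-style barcodes identify platform-specific aliquots; merging layers
#' across platforms requires truncation to a common prefix (e.g. 12
#' characters for patient-level TCGA IDs). Default is no truncation.
#'
#' @param ids Character vector of sample identifiers.
#' @param prefix Prefix length, or `NULL` for exact matching.
#' @export
truncate_barcodes <- function(ids, prefix = NULL) {
  if (is.null(prefix)) ids else substr(ids, 1L, prefix)
}

#' Assemble an aligned multi-omics cohort
#'
#' Restricts every supplied layer to the samples present in the clinical
#' table. Layers keep their own (possibly smaller) sample list, mirroring
#' real multi-platform cohorts where per-layer availability differs.
#'
#' @param name Cohort name.
#' @param expression Numeric matrix, genes x samples (required).
#' @param clinical Clinical data.frame with `sample_id` (required).
#' @param cn,mutations Optional matrices, genes x samples.
#' @param mirna Optional miRNA matrix (log2), miRNAs x samples.
#' @param mirna_class Optional per-sample labels (`tumor`/`normal`) for the
#'   miRNA layer; normal samples are kept even without clinical rows.
#' @param id_prefix Barcode truncation length applied to every layer's sample
#'   IDs before matching (`NULL` = exact).
#' @return An object of class `cohort`: a list with elements `name`,
#'   `expression`, `cn`, `mutations`, `mirna`, `mirna_class`, `clinical`,
#'   `layer_n` (per-layer sample counts).
#' @export
cohort <- function(name, expression, clinical, cn = NULL, mutations = NULL,
                   mirna = NULL, mirna_class = NULL, id_prefix = NULL) {
  fix <- function(m) {
    if (is.null(m)) return(NULL)
    colnames(m) <- truncate_barcodes(colnames(m), id_prefix)
    if (anyDuplicated(colnames(m))) stop("barcode truncation produced duplicate sample IDs")
    m
  }
  expression <- fix(expression); cn <- fix(cn)
  mutations <- fix(mutations); mirna <- fix(mirna)
  clinical$sample_id <- truncate_barcodes(clinical$sample_id, id_prefix)
  keep <- intersect(colnames(expression), clinical$sample_id)
  if (!length(keep)) stop("empty intersection of expression and clinical samples")
  sub <- function(m) {
    if (is.null(m)) return(NULL)
    s <- intersect(colnames(m), clinical$sample_id)
    m[, s, drop = FALSE]
  }
  std <- attr(expression, "standardized")
  expression <- expression[, keep, drop = FALSE]
  attr(expression, "standardized") <- isTRUE(std)
  cn <- sub(cn); mutations <- sub(mutations)
  if (!is.null(mirna)) {
    if (is.null(mirna_class)) {
      mirna_class <- stats::setNames(rep("tumor", ncol(mirna)), colnames(mirna))
    }
    tum <- intersect(colnames(mirna)[mirna_class[colnames(mirna)] == "tumor"],
                     clinical$sample_id)
    nrm <- colnames(mirna)[mirna_class[colnames(mirna)] == "normal"]
    mirna <- mirna[, c(tum, nrm), drop = FALSE]
    mirna_class <- mirna_class[colnames(mirna)]
  }
  clinical <- clinical[clinical$sample_id %in% keep, , drop = FALSE]
  obj <- list(name = name, expression = expression, cn = cn,
              mutations = mutations, mirna = mirna,
              mirna_class = mirna_class, clinical = clinical,
              layer_n = c(expression = ncol(expression),
                          cn = if (is.null(cn)) NA_integer_ else ncol(cn),
                          mutations = if (is.null(mutations)) NA_integer_ else ncol(mutations),
                          mirna = if (is.null(mirna)) NA_integer_ else sum(mirna_class == "tumor"),
                          clinical = nrow(clinical)))
  class(obj) <- "cohort"
  obj
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort '", x$name, "': ", ncol(x$expression), " samples, ",
      nrow(x$expression), " genes\n", sep = "")
  n <- x$layer_n[!is.na(x$layer_n)]
  cat("  layers:", paste(names(n), n, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Match a gene signature against a cohort's expression platform
#'
#' Returns the subset of signature genes measured in the cohort and the
#' coverage fraction. Classification with poor coverage is unreliable, so
#' coverage below `floor` is an error.
#'
#' @param cohort A `cohort` object or an expression matrix.
#' @param genes Character vector of signature gene symbols.
#' @param floor Minimum acceptable coverage fraction (default 0.5).
#' @return List with `genes` (present subset, signature order) and
#'   `coverage` (fraction present).
#' @export
match_signature_genes <- function(cohort, genes, floor = 0.5) {
  expr <- if (inherits(cohort, "cohort")) cohort$expression else cohort
  genes <- toupper(genes)
  present <- genes[genes %in% rownames(expr)]
  coverage <- length(present) / length(genes)
  if (coverage < floor) {
    stop(sprintf(
      "signature coverage %.2f below floor %.2f: classification not advised",
      coverage, floor))
  }
  list(genes = present, coverage = coverage)
}
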