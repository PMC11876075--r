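# All in-memory genomic coordinates are 0-based half-open [start, end),
# matching BED/narrowPeak. Summits are stored as absolute 0-based
# coordinates (not offsets) so they survive merging arithmetic; they are
# converted back to offsets on write.

#' Read an ENCODE narrowPeak (BED6+4) file
#'
#' Peaks are returned with absolute summit coordinates. A summit offset of
#' -1 (peak caller did not report a summit) is replaced by the interval
#' midpoint, with a warning.
#'
#' @param path Path to a narrowPeak file.
#' @param source Optional population/replicate label attached to every peak;
#'   defaults to the file name without extension.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `signal`, `pvalue`, `qvalue`, `summit` (absolute,
#'   0-based) and `source`.
#' @export
read_narrowpeak <- function(path, source = NULL) {
  if (is.null(source)) source <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_peaks(source))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 10L)) {
    stop("malformed narrowPeak line ", which(nf < 10L)[1L], " in ", path,
         ": expected 10 fields, got ", nf[which(nf < 10L)[1L]])
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  offset <- suppressWarnings(as.integer(m[, 10L]))
  bad <- which(is.na(start) | is.na(end) | is.na(offset))
  if (length(bad) > 0L) {
    stop("malformed narrowPeak line ", bad[1L], " in ", path,
         ": non-numeric coordinate or summit field")
  }
  if (any(start >= end)) {
    stop("invalid interval at line ", which(start >= end)[1L], " in ", path,
         ": start >= end")
  }
  summit <- ifelse(offset >= 0L, start + offset, (start + end) %/% 2L)
  if (any(offset < 0L)) {
    warning(sum(offset < 0L), " peak(s) without a reported summit in ",
            basename(path), "; using interval midpoints")
  }
  out_of_peak <- summit < start | summit >= end
  if (any(out_of_peak)) {
    stop("summit outside its peak at line ", which(out_of_peak)[1L],
         " in ", path)
  }
  data.frame(
    chrom = m[, 1L], start = start, end = end, name = m[, 4L],
    score = as.numeric(m[, 5L]), strand = m[, 6L],
    signal = as.numeric(m[, 7L]), pvalue = as.numeric(m[, 8L]),
    qvalue = as.numeric(m[, 9L]), summit = as.integer(summit),
    source = source, stringsAsFactors = FALSE
  )
}

empty_peaks <- function(source = character(0)) {
  data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    name = character(0), score = numeric(0), strand = character(0),
    signal = numeric(0), pvalue = numeric(0), qvalue = numeric(0),
    summit = integer(0), source = character(0), stringsAsFactors = FALSE
  )
}

#' Write peaks to a narrowPeak file
#'
#' Absolute summit coordinates are converted back to offsets from the peak
#' start, so `read_narrowpeak(write_atlas(x))` is the identity on the
#' coordinate columns.
#'
#' @param atlas A peak `data.frame` as returned by [read_narrowpeak()] or
#'   [build_atlas()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(is.data.frame(atlas))
  if (nrow(atlas) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  name <- if ("name" %in% names(atlas)) atlas$name else
    paste0("peak_", seq_len(nrow(atlas)))
  lines <- paste(
    atlas$chrom, atlas$start, atlas$end, name,
    if ("score" %in% names(atlas)) atlas$score else 0,
    if ("strand" %in% names(atlas)) atlas$strand else ".",
    if ("signal" %in% names(atlas)) atlas$signal else 0,
    if ("pvalue" %in% names(atlas)) atlas$pvalue else -1,
    if ("qvalue" %in% names(atlas)) atlas$qvalue else -1,
    atlas$summit - atlas$start,
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read position weight matrices in MEME minimal motif format
#'
#' Parses the letter-probability matrices of a MEME minimal file into a
#' list of PWM objects. Probability rows off unit sum by at most `tol` are
#' renormalized; larger deviations are an error. TF gene symbols and
#' protein family labels can be supplied through `annotation` (keyed by
#' motif name); unannotated motifs get `tf_gene = name` and `family = NA`.
#'
#' @param path Path to a MEME minimal format file.
#' @param annotation Optional `data.frame` with columns `motif`, `tf_gene`,
#'   `family`.
#' @param tol Maximum tolerated deviation of a row sum from 1 (default 1e-3).
#' @return A list of `pwm` objects: `list(name, tf_gene, family, matrix)`
#'   with `matrix` an L x 4 probability matrix over A, C, G, T.
#' @export
read_meme_pwms <- function(path, annotation = NULL, tol = 1e-3) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\b", lines)
  pwms <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    hdr <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1L]]
    name <- hdr[2L]
    j <- starts[i] + 1L
    while (j <= length(lines) && !grepl("^letter-probability", lines[j])) j <- j + 1L
    if (j > length(lines)) stop("motif ", name, " has no letter-probability matrix")
    rows <- list()
    j <- j + 1L
    while (j <= length(lines)) {
      ln <- trimws(lines[j])
      if (!nzchar(ln) || grepl("^(MOTIF|URL)\\b", lines[j])) break
      vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1L]]))
      if (anyNA(vals)) stop("non-numeric probability in motif ", name)
      if (length(vals) != 4L) stop("motif ", name, ": expected 4 columns, got ",
                                   length(vals))
      rows[[length(rows) + 1L]] <- vals
      j <- j + 1L
    }
    mat <- do.call(rbind, rows)
    if (is.null(mat) || nrow(mat) < 1L) stop("motif ", name, " is empty")
    if (any(mat < 0)) stop("negative probability in motif ", name)
    rs <- rowSums(mat)
    if (any(rs == 0)) stop("motif ", name, " has an all-zero row")
    if (any(abs(rs - 1) > tol)) {
      stop("motif ", name, " row sum deviates from 1 by more than ", tol)
    }
    mat <- mat / rs
    colnames(mat) <- c("A", "C", "G", "T")
    pwms[[i]] <- new_pwm(name, mat)
  }
  if (!is.null(annotation)) {
    idx <- match(vapply(pwms, `[[`, "", "name"), annotation$motif)
    for (i in seq_along(pwms)) {
      if (!is.na(idx[i])) {
        pwms[[i]]$tf_gene <- annotation$tf_gene[idx[i]]
        pwms[[i]]$family <- annotation$family[idx[i]]
      }
    }
  }
  pwms
}

new_pwm <- function(name, matrix, tf_gene = name, family = NA_character_) {
  stopifnot(ncol(matrix) == 4L, all(matrix >= 0))
  colnames(matrix) <- c("A", "C", "G", "T")
  structure(list(name = name, tf_gene = tf_gene, family = family,
                 matrix = matrix), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$name, "(gene", x$tf_gene, ", family",
      ifelse(is.na(x$family), "<none>", x$family), ", length",
      nrow(x$matrix), ")\n")
  invisible(x)
}

#' Write PWMs in MEME minimal format
#'
#' @param pwms List of `pwm` objects.
#' @param path Output path.
#' @param background Background frequencies written to the header
#'   (default uniform).
#' @return `path`, invisibly.
#' @export
write_meme_pwms <- function(pwms, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", background[1],
                       background[2], background[3], background[4]), ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       nrow(p$matrix)), con)
    writeLines(apply(p$matrix, 1L, function(r) sprintf(" %.6f %.6f %.6f %.6f",
                                                       r[1], r[2], r[3], r[4])), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a sample-annotated FPKM expression table
#'
#' @param path TSV with a `gene` column and one column per sample.
#' @param populations Named character vector mapping sample -> population.
#' @return A list with `values` (gene x sample numeric matrix), `genes`,
#'   `samples` and `populations`.
#' @export
read_expression <- function(path, populations) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot("gene" %in% names(tab))
  values <- as.matrix(tab[, setdiff(names(tab), "gene"), drop = FALSE])
  rownames(values) <- tab$gene
  if (any(values < 0)) stop("negative FPKM values in ", path)
  missing <- setdiff(colnames(values), names(populations))
  if (length(missing) > 0L) {
    stop("samples without a population assignment: ",
         paste(missing, collapse = ", "))
  }
  list(values = values, genes = tab$gene, samples = colnames(values),
       populations = populations[colnames(values)])
}

#' Read a differential table (log2FC and adjusted p per comparison)
#'
#' @param path TSV with columns `feature` and, per comparison `c`,
#'   `log2fc_<c>` and `padj_<c>`.
#' @return A `data.frame`; attribute `comparisons` lists the comparisons.
#' @export
read_differential <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot("feature" %in% names(tab))
  if (anyDuplicated(tab$feature)) stop("duplicate feature ids in ", path)
  comps <- sub("^log2fc_", "", grep("^log2fc_", names(tab), value = TRUE))
  for (cc in comps) {
    pcol <- paste0("padj_", cc)
    if (pcol %in% names(tab)) {
      bad <- !is.na(tab[[pcol]]) & (tab[[pcol]] < 0 | tab[[pcol]] > 1)
      if (any(bad)) stop("padj outside [0, 1] in ", path)
    }
  }
  attr(tab, "comparisons") <- comps
  tab
}

#' Read a flat clonotype table
#'
#' One row per cell chain: columns `cell_id`, `mouse_id`, `phenotype`,
#' `chain` (for example TRA/TRB) and `cdr3_nt`.
#'
#' @param path TSV path.
#' @return A `data.frame` of chain records.
#' @export
read_clonotype_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "mouse_id", "phenotype", "chain", "cdr3_nt")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) stop("clonotype table missing columns: ",
                              paste(miss, collapse = ", "))
  bad <- grepl("[^ACGT]", tab$cdr3_nt)
  if (any(bad)) stop("CDR3 strings must be over {A,C,G,T}; offending row ",
                     which(bad)[1L])
  tab
}

#' Read a cell-by-gene count matrix (MatrixMarket + annotations)
#'
#' @param mtx_path MatrixMarket file, genes x cells.
#' @param genes_path One gene symbol per line.
#' @param cells_path TSV with columns `cell_id` and any label columns.
#' @return List with `counts` (sparse dgCMatrix, genes x cells) and `cells`.
#' @export
read_cell_matrix <- function(mtx_path, genes_path, cells_path) {
  counts <- Matrix::readMM(mtx_path)
  genes <- readLines(genes_path)
  cells <- utils::read.delim(cells_path, stringsAsFactors = FALSE)
  stopifnot(nrow(counts) == length(genes), ncol(counts) == nrow(cells))
  rownames(counts) <- genes
  colnames(counts) <- cells$cell_id
  list(counts = methods::as(counts, "CsparseMatrix"), cells = cells)
}

#' Read gene models (TSS table)
#'
#' Accepts 0-based half-open `tx_start`/`tx_end` columns directly, or a
#' 1-based inclusive GTF-convention table when `one_based = TRUE`, in which
#' case coordinates are converted exactly once here.
#'
#' @param path TSV with columns `gene`, `chrom`, `strand`, `tx_start`,
#'   `tx_end`.
#' @param one_based Set `TRUE` if the file uses 1-based inclusive
#'   coordinates (GTF convention).
#' @return A `data.frame` with 0-based half-open `tx_start`, `tx_end` and a
#'   derived absolute `tss` column (strand-dependent gene 5' end).
#' @export
read_gene_models <- function(path, one_based = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "strand", "tx_start", "tx_end")
  stopifnot(all(need %in% names(tab)))
  if (one_based) {
    tab$tx_start <- tab$tx_start - 1L  # [a, b] 1-based -> [a-1, b) 0-based
  }
  stopifnot(all(tab$strand %in% c("+", "-")))
  tab$tss <- ifelse(tab$strand == "+", tab$tx_start, tab$tx_end - 1L)
  tab
}

#' Read a BED3 interval file (for example a repeat mask)
#'
#' @param path BED3 path.
#' @return `data.frame` with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "[ \t]+")
  m <- do.call(rbind, lapply(fields, `[`, 1:3))
  out <- data.frame(chrom = m[, 1L], start = as.integer(m[, 2L]),
                    end = as.integer(m[, 3L]), stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("invalid BED interval (start >= end)")
  out
}
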