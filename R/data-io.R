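#' Binarize a copy-number amplitude
#'
#' Converts a continuous per-sample alteration amplitude (e.g. a GISTIC2-style
#' log2 copy-number value) into altered / not-altered status. An amplification
#' is called altered when the amplitude strictly exceeds `threshold`; a
#' deletion when it falls strictly below `-threshold`. Amplitudes exactly at
#' the boundary are not altered.
#'
#' @param t Numeric vector of amplitudes. Must be finite.
#' @param direction `"amplification"` or `"deletion"`.
#' @param threshold Positive amplitude cutoff (default 0.1).
#' @return Integer vector of 0/1 status values, same length as `t`.
#' @examples
#' binarize_amplitude(c(0.15, 0.10, -0.2), "amplification")
#' binarize_amplitude(c(-0.15, -0.05), "deletion")
#' @export
binarize_amplitude <- function(t, direction = c("amplification", "deletion"),
                               threshold = 0.1) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t))) {
    stop("amplitudes must be finite numeric values", call. = FALSE)
  }
  if (direction == "amplification") {
    as.integer(t > threshold)
  } else {
    as.integer(t < -threshold)
  }
}

validate_expression <- function(mat, what = "expression matrix") {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop(what, " must have gene rownames and sample colnames", call. = FALSE)
  }
  dup_g <- rownames(mat)[duplicated(rownames(mat))]
  if (length(dup_g)) {
    stop("duplicate gene identifiers: ", paste(unique(dup_g), collapse = ", "),
         call. = FALSE)
  }
  dup_s <- colnames(mat)[duplicated(colnames(mat))]
  if (length(dup_s)) {
    stop("duplicate sample identifiers: ",
         paste(unique(dup_s), collapse = ", "), call. = FALSE)
  }
  if (ncol(mat) < 2L) stop(what, " needs at least 2 samples", call. = FALSE)
  if (anyNA(mat) || any(!is.finite(mat))) {
    stop(what, " contains missing or non-finite values", call. = FALSE)
  }
  mat
}

#' Read a log2 expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column `gene_id`;
#' all remaining cells numeric log2 expression values.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_expression <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header) || !nzchar(header)) {
    stop("expression file '", path, "' is empty", call. = FALSE)
  }
  fields <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  if (length(fields) < 3L) {
    stop("expression file '", path, "' has fewer than 2 sample columns",
         call. = FALSE)
  }
  samples <- fields[-1L]
  dup <- unique(samples[duplicated(samples)])
  if (length(dup)) {
    stop("duplicate sample identifiers in '", path, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  spec <- c(list(readr::col_character()),
            rep(list(readr::col_double()), length(samples)))
  names(spec) <- fields
  df <- suppressWarnings(
    readr::read_tsv(path, col_types = do.call(readr::cols, spec),
                    name_repair = "minimal", progress = FALSE))
  if (nrow(df) == 0L) {
    stop("expression file '", path, "' has no gene rows", call. = FALSE)
  }
  if (nrow(probs <- readr::problems(df)) > 0L) {
    stop("could not parse '", path, "': non-numeric value at row ",
         probs$row[1L], ", column ", probs$col[1L], call. = FALSE)
  }
  genes <- df[[1L]]
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- genes
  validate_expression(mat, paste0("expression file '", path, "'"))
}

#' Write an expression matrix to TSV
#'
#' @param mat Genes x samples numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

new_alteration_set <- function(info, status, cis_genes) {
  stopifnot(is.matrix(status), nrow(info) == nrow(status),
            all(info$alt_id == rownames(status)),
            all(names(cis_genes) == info$alt_id))
  structure(
    list(info = info, status = status, cis_genes = cis_genes,
         sample_ids = colnames(status)),
    class = "alteration_set"
  )
}

#' Construct an alteration set
#'
#' Bundles the per-alteration binary status matrix with direction labels and
#' cis-gene (wide-peak) membership. Alterations whose status is constant over
#' all samples are retained but flagged unusable for two-group testing.
#'
#' @param info Data frame with columns `alt_id` and `direction`
#'   (`"amplification"`/`"deletion"`).
#' @param status Alterations x samples matrix of 0/1 status, rownames matching
#'   `info$alt_id`, colnames the sample identifiers.
#' @param cis_genes Named list (by `alt_id`) of cis-gene character vectors.
#' @return An `alteration_set` object.
#' @export
alteration_set <- function(info, status, cis_genes) {
  info <- tibble::as_tibble(info)
  stopifnot(all(c("alt_id", "direction") %in% names(info)))
  if (anyDuplicated(info$alt_id)) {
    stop("alteration identifiers must be unique", call. = FALSE)
  }
  bad_dir <- setdiff(unique(info$direction), c("amplification", "deletion"))
  if (length(bad_dir)) {
    stop("unknown alteration direction: ", paste(bad_dir, collapse = ", "),
         call. = FALSE)
  }
  if (!all(status %in% c(0L, 1L))) {
    stop("status values must be 0 or 1", call. = FALSE)
  }
  storage.mode(status) <- "integer"
  missing_cis <- setdiff(info$alt_id, names(cis_genes))
  cis_genes[missing_cis] <- list(character(0))
  extra <- setdiff(names(cis_genes), info$alt_id)
  if (length(extra)) {
    stop("cis map names unknown alteration(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  cis_genes <- cis_genes[info$alt_id]
  n_alt <- unname(rowSums(status))
  info$n_altered <- as.integer(n_alt)
  info$usable <- n_alt > 0L & n_alt < ncol(status)
  new_alteration_set(info, status, cis_genes)
}

#' @export
print.alteration_set <- function(x, ...) {
  cat("<alteration_set> ", nrow(x$info), " alteration(s) x ",
      length(x$sample_ids), " sample(s); ",
      sum(!x$info$usable), " unusable (constant status)\n", sep = "")
  print(x$info, ...)
  invisible(x)
}

#' Read alterations from a lesions table and a cis-gene map
#'
#' The lesions TSV has one row per alteration with columns `alt_id`,
#' `direction` and one numeric column per sample holding either continuous
#' amplitudes (binarized at `threshold`) or pre-binarized 0/1 status. The cis
#' map TSV has columns `alt_id`, `gene_id` listing wide-peak membership.
#'
#' @param lesions_path,cis_map_path Paths to the two TSV files.
#' @param threshold Amplitude cutoff passed to [binarize_amplitude()].
#' @param binarized `TRUE` when the lesions table already holds 0/1 status,
#'   `FALSE` to force binarization, or `NULL` (default) to auto-detect: a
#'   table whose sample columns contain only 0 and 1 is taken as
#'   pre-binarized (re-binarizing it would zero out every deletion row).
#' @return An `alteration_set`.
#' @export
read_alterations <- function(lesions_path, cis_map_path, threshold = 0.1,
                             binarized = NULL) {
  lesions <- readr::read_tsv(lesions_path, col_types = readr::cols(
    alt_id = readr::col_character(), direction = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  stopifnot(all(c("alt_id", "direction") %in% names(lesions)))
  cis_map <- readr::read_tsv(cis_map_path, col_types = readr::cols(
    alt_id = readr::col_character(), gene_id = readr::col_character()
  ), progress = FALSE)
  unknown <- setdiff(unique(cis_map$alt_id), lesions$alt_id)
  if (length(unknown)) {
    stop("cis map names alteration(s) absent from the lesions table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  samp_cols <- setdiff(names(lesions), c("alt_id", "direction"))
  amp <- as.matrix(lesions[, samp_cols, drop = FALSE])
  rownames(amp) <- lesions$alt_id
  if (is.null(binarized)) {
    binarized <- all(amp %in% c(0, 1))
    if (binarized) {
      message("lesions table contains only 0/1 values; ",
              "treating it as pre-binarized status")
    }
  }
  if (binarized) {
    status <- amp
  } else {
    status <- amp
    for (i in seq_len(nrow(lesions))) {
      status[i, ] <- binarize_amplitude(amp[i, ], lesions$direction[i],
                                        threshold)
    }
  }
  cis_genes <- split(cis_map$gene_id, cis_map$alt_id)
  alteration_set(lesions[, c("alt_id", "direction")], status, cis_genes)
}

#' Write an alteration set back to the lesions / cis-map TSV pair
#'
#' @param alts An `alteration_set`.
#' @param lesions_path,cis_map_path Output paths.
#' @return `lesions_path`, invisibly.
#' @export
write_alterations <- function(alts, lesions_path, cis_map_path) {
  lesions <- dplyr::bind_cols(
    alts$info[, c("alt_id", "direction")],
    tibble::as_tibble(alts$status)
  )
  readr::write_tsv(lesions, lesions_path, progress = FALSE)
  cis <- tibble::tibble(
    alt_id = rep(names(alts$cis_genes), lengths(alts$cis_genes)),
    gene_id = unlist(alts$cis_genes, use.names = FALSE)
  )
  readr::write_tsv(cis, cis_map_path, progress = FALSE)
  invisible(lesions_path)
}

#' Partition the expressed-gene universe into cis and trans sets
#'
#' Cis genes are the alteration's wide-peak members present in the expression
#' universe; trans genes are every other expressed gene. The two sets always
#' form a disjoint cover of the universe.
#'
#' @param alts An `alteration_set`.
#' @param alt_id Alteration to partition for.
#' @param universe Character vector of expressed gene identifiers.
#' @return List with character vectors `cis` and `trans`.
#' @export
partition_cis_trans <- function(alts, alt_id, universe) {
  stopifnot(length(universe) > 0L)
  if (!alt_id %in% alts$info$alt_id) {
    stop("unknown alteration '", alt_id, "'", call. = FALSE)
  }
  members <- alts$cis_genes[[alt_id]]
  cis <- intersect(universe, members)
  if (length(members) && !length(cis)) {
    warning("no cis gene of '", alt_id, "' is present in the expression data",
            call. = FALSE)
  }
  list(cis = cis, trans = setdiff(universe, members))
}

#' Harmonize an expression matrix and an alteration set on shared samples
#'
#' Both objects are restricted to the intersection of their sample
#' identifiers, ordered as in the expression matrix.
#'
#' @param expr Genes x samples expression matrix.
#' @param alts An `alteration_set`.
#' @return List with elements `expr` and `alts`.
#' @export
match_samples <- function(expr, alts) {
  common <- intersect(colnames(expr), alts$sample_ids)
  if (length(common) < 2L) {
    stop("fewer than 2 samples shared between expression and alterations",
         call. = FALSE)
  }
  expr <- expr[, common, drop = FALSE]
  status <- alts$status[, common, drop = FALSE]
  out <- alteration_set(alts$info[, c("alt_id", "direction")], status,
                        alts$cis_genes)
  list(expr = expr, alts = out)
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path Path to the `.gmt` file.
#' @param source_name Label for the collection (defaults to the file name).
#' @return Named list of character vectors with attribute `source_name`.
#' @export
read_gmt <- function(path, source_name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("GMT file '", path, "' is empty", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    stop("GMT line(s) with no members: ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(parts, function(p) unique(trimws(p[-(1:2)])))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene-set names in '", path, "'", call. = FALSE)
  }
  attr(sets, "source_name") <- source_name
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a driver-gene reference table
#'
#' TSV with columns `gene`, `class` (one of `oncogene`, `tumor_suppressor`)
#' and `source`.
#'
#' @param path Path to the TSV.
#' @return Tibble with the three columns, duplicates removed.
#' @export
read_driver_reference <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), class = readr::col_character(),
    source = readr::col_character()
  ), progress = FALSE)
  bad <- setdiff(unique(df$class), c("oncogene", "tumor_suppressor"))
  if (length(bad)) {
    stop("driver class must be 'oncogene' or 'tumor_suppressor'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dplyr::distinct(df)
}
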