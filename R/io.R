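#' Read a genotype table
#'
#' Tab- or comma-separated text with a header row of marker IDs and the
#' first column holding individual IDs. Values must be strictly 0/1;
#' offending cells are reported with their coordinates.
#'
#' @param path Path to the file.
#' @param sep Field separator; `"\t"` (default) or `","`.
#' @return A `genotype_table`: list with `individual_ids`, `marker_ids`,
#'   and `values` (N x M integer matrix with dimnames).
#' @export
read_genotypes <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          row.names = NULL, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("read_genotypes: no marker columns in ", path, call. = FALSE)
  ids <- df[[1L]]
  marker_ids <- colnames(df)[-1L]
  if (anyDuplicated(ids))
    stop("read_genotypes: duplicate individual IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(marker_ids))
    stop("read_genotypes: duplicate marker IDs: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "),
         call. = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | !(num == 0 | num == 1))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(num))
    stop("read_genotypes: ", length(bad), " non-{0,1} cell(s); first is value '",
         vals[bad[1L]], "' at individual '", ids[rc[1L]], "', marker '",
         marker_ids[rc[2L]], "'", call. = FALSE)
  }
  values <- matrix(as.integer(num), nrow(num), ncol(num),
                   dimnames = list(ids, marker_ids))
  structure(list(individual_ids = ids, marker_ids = marker_ids, values = values),
            class = "genotype_table")
}

#' Write a genotype table
#'
#' @param g A `genotype_table` or a 0/1 matrix with dimnames.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, sep = "\t") {
  if (inherits(g, "genotype_table")) g <- g$values
  df <- data.frame(id = rownames(g), g, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- "individual"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Header row of trait names, first column individual IDs; empty cells and
#' `"NA"` are missing values (individuals with missing readings for a trait
#' are dropped later, per trait).
#'
#' @param path Path to the file.
#' @param sep Field separator.
#' @return A `phenotype_table`: list with `individual_ids`, `trait_names`,
#'   `values` (N x T numeric matrix, NA = missing) and `missing_per_trait`.
#' @export
read_phenotypes <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          row.names = NULL, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(df) < 2L) stop("read_phenotypes: no trait columns in ", path, call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("read_phenotypes: duplicate individual IDs", call. = FALSE)
  traits <- colnames(df)[-1L]
  values <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  dimnames(values) <- list(ids, traits)
  structure(list(individual_ids = ids, trait_names = traits, values = values,
                 missing_per_trait = colSums(is.na(values))),
            class = "phenotype_table")
}

#' Write a phenotype table
#'
#' @param p A `phenotype_table` or a numeric matrix with dimnames.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(p, path, sep = "\t") {
  if (inherits(p, "phenotype_table")) p <- p$values
  df <- data.frame(individual = rownames(p), p, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align genotypes and one phenotype, dropping missing readings
#'
#' Intersects individual IDs (phenotype rows are matched by ID, never by
#' position), drops individuals with a missing value for the requested
#' trait, and returns rows in genotype-table order.
#'
#' @param g A `genotype_table`.
#' @param p A `phenotype_table`.
#' @param trait Trait name present in `p`.
#' @return List with `X` (0/1 matrix), `t` (numeric vector) and `kept_ids`.
#' @export
align_and_filter <- function(g, p, trait) {
  stopifnot(inherits(g, "genotype_table"), inherits(p, "phenotype_table"))
  if (!trait %in% p$trait_names)
    stop("align_and_filter: trait '", trait, "' not in phenotype table", call. = FALSE)
  shared <- g$individual_ids[g$individual_ids %in% p$individual_ids]
  if (!length(shared))
    stop("align_and_filter: genotype and phenotype tables share no individual IDs",
         call. = FALSE)
  tvals <- p$values[shared, trait]
  keep <- shared[!is.na(tvals)]
  if (length(keep) < 2L)
    stop("align_and_filter: fewer than 2 usable individuals for trait '",
         trait, "'", call. = FALSE)
  list(X = g$values[keep, , drop = FALSE],
       t = unname(p$values[keep, trait]),
       kept_ids = keep)
}

.parse_chr_pos <- function(marker_ids) {
  m <- regmatches(marker_ids, regexec("^(.+):([0-9]+)$", marker_ids))
  ok <- lengths(m) == 3L
  list(ok = ok,
       chrom = ifelse(ok, vapply(m, function(x) if (length(x) == 3L) x[2L] else NA_character_, character(1)), NA_character_),
       pos = ifelse(ok, suppressWarnings(as.integer(
         vapply(m, function(x) if (length(x) == 3L) x[3L] else NA_character_, character(1)))), NA_integer_))
}

#' Write a marker ranking as TSV or BED
#'
#' TSV columns: `marker_id, chrom, pos, count, rank_fraction, mean_weight,
#' sign, rank_order` (positions 1-based as in the marker IDs). BED output
#' is 0-based half-open (`start = pos - 1`, `end = pos`) with
#' `score = round(1000 * rank_fraction)` for genome-browser display.
#'
#' @param ranking A `marker_ranking` from [rank_markers()].
#' @param marker_ids Character vector of marker IDs for all M markers
#'   (e.g. `g$marker_ids` or `colnames(X)`); IDs of the form `"chr:pos"`
#'   populate the coordinate columns and are required for BED.
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, marker_ids, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  stopifnot(inherits(ranking, "marker_ranking"))
  if (length(marker_ids) < attr(ranking, "n_markers"))
    stop("write_ranking: marker_ids shorter than the ranked marker space",
         call. = FALSE)
  ids <- marker_ids[ranking$marker]
  cp <- .parse_chr_pos(ids)
  if (format == "bed") {
    if (!all(cp$ok))
      stop("write_ranking: BED output requires all marker IDs in 'chr:pos' ",
           "form; first offender: '", ids[which(!cp$ok)[1L]], "'", call. = FALSE)
    bed <- data.frame(chrom = cp$chrom,
                      start = cp$pos - 1L,
                      end = cp$pos,
                      name = ids,
                      score = as.integer(round(1000 * ranking$rank_fraction)),
                      stringsAsFactors = FALSE)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    tsv <- data.frame(marker_id = ids,
                      chrom = cp$chrom,
                      pos = cp$pos,
                      count = ranking$count,
                      rank_fraction = ranking$rank_fraction,
                      mean_weight = ranking$mean_weight,
                      sign = ranking$sign,
                      rank_order = ranking$rank_order,
                      stringsAsFactors = FALSE)
    utils::write.table(tsv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Serialize a fitted RVM to a JSON file
#'
#' Self-describing archive holding the basis kind, kernel parameters,
#' relevance indices and weights, noise variance, target centering, and —
#' for kernel models — the genotype rows of the relevance vectors only.
#'
#' @param model An `rvm` from [rvm()].
#' @param path Output path (".json").
#' @return `path`, invisibly.
#' @export
write_rvm_model <- function(model, path) {
  stopifnot(inherits(model, "rvm"))
  obj <- list(format = "rvmsel_model", version = 1L,
              basis_kind = model$basis_kind,
              kernel = if (!is.null(model$kernel)) unclass(model$kernel),
              active = model$active,
              column_meaning = model$column_meaning,
              weights = model$weights,
              sigma2 = model$sigma2,
              target_mean = model$target_mean,
              n_features = model$n_features,
              n_train = model$n_train,
              rv_index = model$rv_index,
              rv_inputs = if (!is.null(model$rv_inputs))
                unname(as.matrix(model$rv_inputs)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a fitted RVM from a JSON file
#'
#' @param path Path written by [write_rvm_model()].
#' @return An `rvm` object usable with [predict.rvm()].
#' @export
read_rvm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "rvmsel_model"))
    stop("read_rvm_model: ", path, " is not an rvmsel model archive", call. = FALSE)
  model <- list(basis_kind = obj$basis_kind,
                active = as.integer(obj$active),
                column_meaning = obj$column_meaning,
                weights = as.numeric(obj$weights),
                sigma2 = obj$sigma2,
                target_mean = obj$target_mean,
                n_features = obj$n_features,
                n_train = obj$n_train,
                notes = NULL)
  if (!is.null(obj$kernel))
    model$kernel <- structure(obj$kernel, class = "kernel_spec")
  if (!is.null(obj$rv_index)) model$rv_index <- as.integer(obj$rv_index)
  if (!is.null(obj$rv_inputs)) model$rv_inputs <- as.matrix(obj$rv_inputs)
  structure(model, class = "rvm")
}
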