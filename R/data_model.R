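#' Describe a microsatellite locus
#'
#' @param name Locus name.
#' @param repeat_unit Repeat motif length in bp (2 for GT dinucleotides).
#' @param size_min,size_max Optional expected fragment-size range in bp.
#' @return One-row data frame with columns `name`, `repeat_unit`,
#'   `size_min`, `size_max`.
#' @export
locus_info <- function(name, repeat_unit, size_min = NA_integer_,
                       size_max = NA_integer_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  repeat_unit <- as.integer(repeat_unit)
  if (is.na(repeat_unit) || repeat_unit < 1L)
    stop("repeat_unit must be an integer >= 1", call. = FALSE)
  if (!is.na(size_min) && !is.na(size_max) && size_min > size_max)
    stop("size_min must not exceed size_max", call. = FALSE)
  data.frame(name = name, repeat_unit = repeat_unit,
             size_min = as.integer(size_min), size_max = as.integer(size_max),
             stringsAsFactors = FALSE)
}

#' Assemble a mixed-ploidy microsatellite dataset
#'
#' The central genotype container. Allele dosage is unobservable in
#' polyploid fragment data, so a genotype at a locus is a *set* of distinct
#' fragment sizes (1 up to the individual's ploidy), or missing.
#'
#' @param loci Data frame of loci as built by [locus_info()] (rows may be
#'   concatenated with `rbind`).
#' @param populations Data frame with at least a column `id`; optional
#'   columns `region`, `status`, `latitude`, `longitude`, `elevation`.
#' @param individuals Data frame with columns `id` and `population`.
#' @param calls List indexed by locus name; each element a list indexed by
#'   individual id holding an integer vector of distinct allele sizes, or
#'   `NULL` for missing.
#' @param max_ploidy Maximum allowed number of distinct alleles per
#'   genotype (default 8).
#' @return An object of class `microsat_dataset`.
#' @export
microsat_dataset <- function(loci, populations, individuals, calls,
                             max_ploidy = 8L) {
  stopifnot(is.data.frame(loci), is.data.frame(populations),
            is.data.frame(individuals), is.list(calls))
  if (anyDuplicated(loci$name)) stop("duplicated locus names", call. = FALSE)
  if (anyDuplicated(populations$id))
    stop("duplicated population ids", call. = FALSE)
  if (anyDuplicated(individuals$id))
    stop("duplicated individual ids", call. = FALSE)
  bad_pop <- setdiff(individuals$population, populations$id)
  if (length(bad_pop))
    stop("individuals reference unknown populations: ",
         paste(bad_pop, collapse = ", "), call. = FALSE)
  if (!is.null(populations$latitude) &&
      any(abs(populations$latitude) > 90, na.rm = TRUE))
    stop("latitude out of range", call. = FALSE)
  if (!is.null(populations$longitude) &&
      any(abs(populations$longitude) > 180, na.rm = TRUE))
    stop("longitude out of range", call. = FALSE)
  if (!setequal(names(calls), loci$name))
    stop("calls must have one element per locus", call. = FALSE)
  calls <- calls[loci$name]
  for (loc in loci$name) {
    cl <- calls[[loc]]
    missing_ids <- setdiff(individuals$id, names(cl))
    if (length(missing_ids)) {
      cl[missing_ids] <- list(NULL)
    }
    cl <- cl[individuals$id]
    cl <- lapply(cl, function(a) {
      if (is.null(a) || length(a) == 0L) return(NULL)
      a <- sort(unique(as.integer(a)))
      if (any(is.na(a)) || any(a <= 0L))
        stop("allele sizes must be positive integers", call. = FALSE)
      if (length(a) > max_ploidy)
        stop("allele set exceeds max ploidy (", max_ploidy, ")",
             call. = FALSE)
      a
    })
    calls[[loc]] <- cl
  }
  structure(list(loci = loci, populations = populations,
                 individuals = individuals, calls = calls,
                 max_ploidy = as.integer(max_ploidy)),
            class = "microsat_dataset")
}

#' @export
print.microsat_dataset <- function(x, ...) {
  cat("microsat_dataset:", nrow(x$individuals), "individuals,",
      nrow(x$populations), "populations,", nrow(x$loci), "loci\n")
  n_missing <- sum(vapply(x$calls, function(cl)
    sum(vapply(cl, is.null, logical(1))), numeric(1)))
  cat("  missing genotypes:", n_missing, "of",
      nrow(x$individuals) * nrow(x$loci), "\n")
  invisible(x)
}

#' Population labels of the individuals in a dataset
#' @param dataset A `microsat_dataset`.
#' @return Character vector named by individual id.
#' @export
population_of <- function(dataset) {
  stats::setNames(dataset$individuals$population, dataset$individuals$id)
}

# ---- genotype file i/o ------------------------------------------------------

#' Write a genotype table
#'
#' Wide CSV with a comment header block describing the loci
#' (`# locus,<name>,<repeat_unit>,<columns>[,<min>,<max>]`) followed by one
#' row per individual: id, population, then per-locus allele columns. Blank
#' cells pad genotypes with fewer alleles than the column count; a fully
#' blank locus is a missing genotype.
#'
#' @param dataset A `microsat_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(dataset, path) {
  loci <- dataset$loci
  ncols <- vapply(loci$name, function(loc) {
    max(1L, max(vapply(dataset$calls[[loc]], length, integer(1))))
  }, integer(1))
  ncols <- pmax(ncols, 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# polydiff genotypes v1", con)
  for (i in seq_len(nrow(loci))) {
    extra <- if (!is.na(loci$size_min[i]))
      paste0(",", loci$size_min[i], ",", loci$size_max[i]) else ""
    writeLines(sprintf("# locus,%s,%d,%d%s", loci$name[i],
                       loci$repeat_unit[i], ncols[i], extra), con)
  }
  header <- c("individual", "population",
              unlist(lapply(seq_len(nrow(loci)), function(i)
                paste0(loci$name[i], ".", seq_len(ncols[i])))))
  writeLines(paste(header, collapse = ","), con)
  for (j in seq_len(nrow(dataset$individuals))) {
    ind <- dataset$individuals$id[j]
    cells <- unlist(lapply(seq_len(nrow(loci)), function(i) {
      a <- dataset$calls[[loci$name[i]]][[ind]]
      out <- rep("", ncols[i])
      if (!is.null(a)) out[seq_along(a)] <- as.character(a)
      out
    }))
    writeLines(paste(c(ind, dataset$individuals$population[j], cells),
                     collapse = ","), con)
  }
  invisible(path)
}

#' Read a genotype table
#'
#' Counterpart of [write_genotypes()]. Locus metadata is taken from the
#' comment header unless `loci_spec` is supplied.
#'
#' @param path File written by [write_genotypes()] (or hand-built in the
#'   same dialect).
#' @param loci_spec Optional data frame of loci overriding the header block.
#' @param populations Optional data frame of known populations; rows naming
#'   a population absent from it are rejected.
#' @param max_ploidy Maximum allowed distinct alleles per genotype.
#' @return A `microsat_dataset`.
#' @export
read_genotypes <- function(path, loci_spec = NULL, populations = NULL,
                           max_ploidy = 8L) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  locus_lines <- lines[is_comment & startsWith(lines, "# locus,")]
  header_loci <- NULL
  if (length(locus_lines)) {
    parts <- strsplit(sub("^# locus,", "", locus_lines), ",", fixed = TRUE)
    header_loci <- do.call(rbind, lapply(parts, function(p) {
      data.frame(name = p[1], repeat_unit = as.integer(p[2]),
                 ncols = as.integer(p[3]),
                 size_min = if (length(p) >= 5) as.integer(p[4]) else NA_integer_,
                 size_max = if (length(p) >= 5) as.integer(p[5]) else NA_integer_,
                 stringsAsFactors = FALSE)
    }))
  }
  loci <- if (!is.null(loci_spec)) loci_spec else
    header_loci[, c("name", "repeat_unit", "size_min", "size_max")]
  if (is.null(loci))
    stop("no locus metadata in header and no loci_spec given", call. = FALSE)

  body <- lines[!is_comment]
  body_lineno <- which(!is_comment)
  if (!length(body)) stop("no data rows", call. = FALSE)
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (!identical(header[1:2], c("individual", "population")))
    stop("expected header starting 'individual,population'", call. = FALSE)
  # map allele columns to loci by prefix before the final .k suffix
  allele_cols <- header[-(1:2)]
  col_locus <- sub("\\.[0-9]+$", "", allele_cols)
  unknown <- setdiff(unique(col_locus), loci$name)
  if (length(unknown))
    stop("allele columns for undeclared loci: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  rows <- strsplit(body[-1], ",", fixed = TRUE)
  n_fields <- length(header)
  inds <- character(length(rows)); pops <- character(length(rows))
  calls <- lapply(loci$name, function(loc) vector("list", length(rows)))
  names(calls) <- loci$name
  for (r in seq_along(rows)) {
    fields <- rows[[r]]
    # trailing empty cells may be dropped by strsplit; pad
    if (length(fields) < n_fields)
      fields <- c(fields, rep("", n_fields - length(fields)))
    if (length(fields) > n_fields)
      stop("malformed row at line ", body_lineno[r + 1L],
           ": expected ", n_fields, " fields, got ", length(fields),
           call. = FALSE)
    inds[r] <- trimws(fields[1]); pops[r] <- trimws(fields[2])
    cells <- trimws(fields[-(1:2)])
    for (loc in loci$name) {
      vals <- cells[col_locus == loc]
      vals <- vals[nzchar(vals)]
      if (!length(vals)) next
      if (any(!grepl("^[0-9]+$", vals)))
        stop("non-integer allele size at line ", body_lineno[r + 1L],
             " (locus ", loc, ")", call. = FALSE)
      calls[[loc]][[r]] <- as.integer(vals)
    }
  }
  for (loc in loci$name) names(calls[[loc]]) <- inds
  if (is.null(populations)) {
    populations <- data.frame(id = unique(pops), stringsAsFactors = FALSE)
  } else {
    bad <- setdiff(unique(pops), populations$id)
    if (length(bad))
      stop("unknown populations in genotype file: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  microsat_dataset(loci = loci, populations = populations,
                   individuals = data.frame(id = inds, population = pops,
                                            stringsAsFactors = FALSE),
                   calls = calls, max_ploidy = max_ploidy)
}

# ---- phenotype file i/o -----------------------------------------------------

#' Names of the seven morphometric traits
#'
#' Plant height (cm), stem diameter (mm), fresh and dry mass of flowers and
#' seeds (g), internode length (cm), leaf length (cm), leaf width (cm).
#' @return Character vector of trait column names.
#' @export
trait_names <- function() {
  c("plant_height", "stem_diameter", "fresh_mass", "dry_mass",
    "internode_length", "leaf_length", "leaf_width")
}

#' Validate a phenotype table
#'
#' Checks the region > population > haplotype > plant nesting columns and
#' non-negativity of trait values. Missing trait values (`NA`) are allowed.
#'
#' @param table Data frame with columns `region`, `population`, `haplotype`,
#'   `plant`, optionally `replicate`, plus numeric trait columns.
#' @return `table`, with trait column names recorded in the
#'   `"traits"` attribute.
#' @export
validate_phenotypes <- function(table) {
  need <- c("region", "population", "haplotype", "plant")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("phenotype table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  traits <- setdiff(names(table), c(need, "replicate"))
  if (!length(traits)) stop("no trait columns", call. = FALSE)
  for (tr in traits) {
    if (!is.numeric(table[[tr]]))
      stop("trait column '", tr, "' is not numeric", call. = FALSE)
    if (any(table[[tr]] < 0, na.rm = TRUE))
      stop("negative value in trait '", tr, "'", call. = FALSE)
  }
  if (any(!nzchar(as.character(table$population))) ||
      any(!nzchar(as.character(table$plant))))
    stop("empty nesting labels", call. = FALSE)
  key <- if ("replicate" %in% names(table))
    paste(table$population, table$plant, table$replicate) else
      paste(table$population, table$plant)
  if (anyDuplicated(key))
    stop("duplicated (population, plant) key", call. = FALSE)
  attr(table, "traits") <- traits
  table
}

#' Read a phenotype table
#' @param path CSV with header `region,population,haplotype,plant` (plus
#'   optionally `replicate`) and one numeric column per trait.
#' @return Validated data frame (see [validate_phenotypes()]).
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_phenotypes(tab)
}

#' Write a phenotype table
#' @param table Phenotype data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# ---- coordinates ------------------------------------------------------------

#' Parse degrees-minutes-seconds coordinates
#'
#' Accepts strings like `"34°5'19\" N"` or `"W 70°5'41\""`, with the
#' hemisphere letter before or after the numeric part and either ASCII or
#' typographic prime marks. West and South are negative.
#'
#' @param coordinate Character vector of DMS strings.
#' @return Numeric vector of decimal degrees.
#' @export
parse_dms <- function(coordinate) {
  vapply(coordinate, function(s) {
    s0 <- trimws(s)
    hemi <- regmatches(s0, regexpr("[NSEW]", s0))
    if (!length(hemi)) stop("no hemisphere letter in '", s, "'", call. = FALSE)
    nums <- regmatches(s0, gregexpr("[0-9]+(\\.[0-9]+)?", s0))[[1]]
    if (length(nums) < 1L || length(nums) > 3L)
      stop("cannot parse DMS coordinate '", s, "'", call. = FALSE)
    nums <- as.numeric(nums)
    deg <- nums[1]
    min <- if (length(nums) >= 2) nums[2] else 0
    sec <- if (length(nums) >= 3) nums[3] else 0
    if (min >= 60 || sec >= 60)
      stop("minutes/seconds must be < 60 in '", s, "'", call. = FALSE)
    dec <- deg + min / 60 + sec / 3600
    if (hemi %in% c("S", "W")) dec <- -dec
    dec
  }, numeric(1), USE.NAMES = FALSE)
}

# ---- distance matrices ------------------------------------------------------

#' Construct a labeled distance matrix
#'
#' @param values Square numeric matrix (symmetric, zero diagonal,
#'   non-negative entries).
#' @param labels Optional labels; default taken from `dimnames`.
#' @param tol Symmetry tolerance.
#' @return Matrix with `dimnames`, class `dist_matrix`.
#' @export
dist_matrix <- function(values, labels = NULL, tol = 1e-8) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix not square", call. = FALSE)
  if (is.null(labels)) labels <- rownames(values)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(values)))
  if (length(labels) != nrow(values))
    stop("label count does not match dimension", call. = FALSE)
  if (max(abs(values - t(values)), na.rm = TRUE) > tol)
    stop("matrix not symmetric", call. = FALSE)
  if (any(abs(diag(values)) > tol, na.rm = TRUE))
    stop("diagonal not zero", call. = FALSE)
  if (any(values < -tol, na.rm = TRUE))
    stop("negative distances", call. = FALSE)
  values <- (values + t(values)) / 2
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  class(values) <- c("dist_matrix", "matrix", "array")
  values
}

#' Read / write labeled distance matrices
#'
#' CSV form: first column holds labels, header repeats them. PHYLIP form:
#' first line the matrix order, then label + row values (square format).
#'
#' @param m A distance matrix (coerced through [dist_matrix()]).
#' @param path File path.
#' @return The matrix (readers) or `path` invisibly (writers).
#' @name dist_io
NULL

#' @rdname dist_io
#' @export
write_dist_csv <- function(m, path) {
  m <- dist_matrix(unclass(m))
  df <- data.frame(label = rownames(m), as.data.frame(unclass(m),
                                                      check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname dist_io
#' @export
read_dist_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- labels
  dist_matrix(m, labels)
}

#' @rdname dist_io
#' @export
write_dist_phylip <- function(m, path) {
  m <- dist_matrix(unclass(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    lab <- formatC(substr(rownames(m)[i], 1, 10), width = -10)
    writeLines(paste0(lab, paste(sprintf("%.6f", m[i, ]), collapse = "  ")),
               con)
  }
  invisible(path)
}

#' @rdname dist_io
#' @export
read_dist_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  labels <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1]]
    labels[i] <- fields[1]
    m[i, ] <- as.numeric(fields[-1])
  }
  dist_matrix(m, labels)
}
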