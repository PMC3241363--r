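#' Read a feature table and its metadata from delimited text
#'
#' Expects three files: an intensity matrix (header row of metabolite ids,
#' first column of sample ids), a metadata table keyed by `sample_id`, and an
#' optional metabolite annotation sidecar with columns `metabolite_id`,
#' `identified`, `platform`. CSV and TSV are auto-detected from the file
#' extension (`.tsv`/`.tab` means tab, anything else comma). Cells that do not
#' parse as numbers become missing values.
#'
#' @param path intensity matrix file.
#' @param meta_path metadata file with at least `sample_id` and `group`
#'   columns (optionally `study`, `sex`, `age`).
#' @param annotation_path optional annotation sidecar; when absent all
#'   metabolites are treated as identified with unknown platform.
#' @return list with elements `table` (a [feature_table()]) and `meta`
#'   (aligned metadata `data.frame`).
#' @seealso [write_feature_table()]
#' @export
read_feature_table <- function(path, meta_path, annotation_path = NULL) {
  for (p in c(path, meta_path, annotation_path))
    if (!file.exists(p)) stop("file not found: ", p)

  raw <- read_delim_auto(path, as_character = TRUE)
  if (anyDuplicated(raw[[1]]))
    stop("duplicate sample ids: ",
         paste(unique(raw[[1]][duplicated(raw[[1]])]), collapse = ", "))
  x <- suppressWarnings(
    vapply(raw[-1], function(col) as.numeric(col), numeric(nrow(raw)))
  )
  x <- matrix(x, nrow = nrow(raw),
              dimnames = list(raw[[1]], colnames(raw)[-1]))

  identified <- NULL
  platform <- NULL
  if (!is.null(annotation_path)) {
    ann <- read_delim_auto(annotation_path)
    need <- c("metabolite_id", "identified")
    if (!all(need %in% colnames(ann)))
      stop("annotation file must have columns metabolite_id and identified")
    idx <- match(colnames(x), ann$metabolite_id)
    if (anyNA(idx))
      stop("annotation missing for metabolite(s): ",
           paste(colnames(x)[is.na(idx)], collapse = ", "))
    identified <- as.logical(ann$identified[idx])
    platform <- if ("platform" %in% colnames(ann)) as.character(ann$platform[idx])
  }
  table <- feature_table(x, identified = identified, platform = platform)

  m <- read_delim_auto(meta_path)
  if (!all(c("sample_id", "group") %in% colnames(m)))
    stop("metadata file must have columns sample_id and group")
  meta <- sample_meta(
    m$sample_id, m$group,
    study = if ("study" %in% colnames(m)) m$study else "study1",
    sex = if ("sex" %in% colnames(m)) m$sex else NA,
    age = if ("age" %in% colnames(m)) m$age else NA
  )
  list(table = table, meta = align_meta(table, meta))
}

#' Write a feature table, metadata and annotation as delimited text
#'
#' Numeric values are written with 15 significant digits so that a
#' write-then-read round trip reproduces the intensities exactly.
#'
#' @param table a `feature_table`
#' @param meta metadata covering `table`
#' @param dir output directory (created if needed)
#' @param prefix file name prefix
#' @param format `"csv"` or `"tsv"`
#' @return (invisibly) named character vector of the three file paths.
#' @export
write_feature_table <- function(table, meta, dir, prefix = "cohort",
                                format = c("csv", "tsv")) {
  stopifnot(inherits(table, "feature_table"))
  format <- match.arg(format)
  meta <- align_meta(table, meta)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sep <- if (format == "tsv") "\t" else ","
  ext <- format

  paths <- c(
    intensities = file.path(dir, sprintf("%s_intensities.%s", prefix, ext)),
    samples = file.path(dir, sprintf("%s_samples.%s", prefix, ext)),
    metabolites = file.path(dir, sprintf("%s_metabolites.%s", prefix, ext))
  )

  num <- format(table$intensities, digits = 15, trim = TRUE, scientific = FALSE)
  num[is.na(table$intensities)] <- ""
  df <- data.frame(sample_id = sample_ids(table), num,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, paths[["intensities"]], sep = sep, row.names = FALSE,
                     quote = TRUE, na = "")
  utils::write.table(meta, paths[["samples"]], sep = sep, row.names = FALSE,
                     quote = TRUE, na = "")
  ann <- data.frame(metabolite_id = metabolite_ids(table),
                    identified = table$identified,
                    platform = table$platform,
                    stringsAsFactors = FALSE)
  utils::write.table(ann, paths[["metabolites"]], sep = sep, row.names = FALSE,
                     quote = TRUE, na = "")
  invisible(paths)
}

read_delim_auto <- function(path, as_character = FALSE) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"",
                    colClasses = if (as_character) "character" else NA,
                    comment.char = "")
}
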