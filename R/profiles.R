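#' Read a raw perturbagen profile table with well metadata
#'
#' Reads a wells-by-features numeric table (first column = well id, header =
#' feature names) together with a metadata table assigning each well to a
#' perturbagen, a role (`"treatment"` or `"control"`), and optionally a plate
#' and a perturbagen type (`"reference"` or `"fraction"`).
#'
#' @param path Path to the delimited profile table.
#' @param meta Either a path to a delimited metadata table or a `data.frame`.
#'   Must contain columns `well` and `role`; optional columns `perturbagen`,
#'   `plate`, `type`, `dose`, `dead_flag`. If `perturbagen` is absent the well
#'   id is used as the perturbagen id.
#' @param sep Field delimiter for both files (default `","`).
#' @param platform Label describing the platform the table came from,
#'   e.g. `"FUSION"` or `"CP"`.
#'
#' @return An object of class `raw_profile_table`: a list with `values`
#'   (numeric matrix, wells x features), `well_meta` (data.frame), and
#'   `platform`.
#' @export
read_profile_table <- function(path, meta, sep = ",", platform = "unknown") {
  if (!file.exists(path)) stop("profile table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("profile table needs an id column plus >=1 feature")
  wells <- tab[[1L]]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) , arr.ind = TRUE)
  # distinguish genuine NA text from unparseable cells; both are rejected
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric or missing value at well '%s', feature '%s'",
                 wells[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
  }
  dimnames(num) <- list(wells, colnames(vals))

  if (is.character(meta)) {
    if (!file.exists(meta)) stop("metadata table not found: ", meta)
    meta <- utils::read.table(meta, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"well" %in% names(meta)) stop("metadata must contain a 'well' column")
  if (!"role" %in% names(meta)) stop("metadata must contain a 'role' column")
  if (!"perturbagen" %in% names(meta)) meta$perturbagen <- meta$well
  miss <- setdiff(wells, meta$well)
  if (length(miss) > 0L)
    stop("wells without metadata: ", paste(utils::head(miss, 5L), collapse = ", "))
  meta <- meta[match(wells, meta$well), , drop = FALSE]
  rownames(meta) <- NULL
  if (any(is.na(meta$role)) || !all(meta$role %in% c("treatment", "control")))
    stop("well roles must be 'treatment' or 'control'")

  new_raw_profile_table(num, meta, platform)
}

new_raw_profile_table <- function(values, well_meta, platform) {
  stopifnot(is.matrix(values), nrow(values) == nrow(well_meta))
  if (ncol(values) == 0L) stop("profile table has no features")
  structure(list(values = values, well_meta = well_meta, platform = platform),
            class = "raw_profile_table")
}

#' Write a profile table (and optional metadata) back to delimited text
#'
#' Inverse of [read_profile_table()]; values round-trip bit-exactly through
#' full-precision decimal formatting.
#'
#' @param x A `raw_profile_table`, `profile_matrix`, or plain numeric matrix.
#' @param path Output path for the value table.
#' @param meta_path Optional output path for well metadata (raw tables only).
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(x, path, meta_path = NULL, sep = ",") {
  m <- if (is.matrix(x)) x else if (inherits(x, "profile_matrix")) x$z else x$values
  df <- data.frame(id = rownames(m),
                   apply(m, 2L, function(col) formatC(col, digits = 17, format = "g")),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", colnames(m))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  if (!is.null(meta_path) && inherits(x, "raw_profile_table"))
    utils::write.table(x$well_meta, meta_path, sep = sep, row.names = FALSE,
                       quote = FALSE)
  invisible(path)
}

#' Z-score normalize a raw profile table against its control wells
#'
#' Within each normalization group (a plate, or the whole table), every
#' feature is centred on the control-well mean and scaled by the control-well
#' sample standard deviation (n - 1 denominator). Replicate treatment wells of
#' the same perturbagen are then averaged into a single row; control wells are
#' dropped from the output. A feature whose control wells are constant gets
#' Z = 0 for the whole group, with a warning.
#'
#' @param raw A `raw_profile_table`.
#' @param group_by `"plate"` to normalize per plate (requires a `plate`
#'   metadata column), `"global"` for one group, or `"auto"` (default:
#'   per-plate when plate ids exist, else global).
#' @param average_replicates Average replicate wells of a perturbagen after
#'   Z-scoring (default `TRUE`).
#'
#' @return An object of class `profile_matrix`: list with `z` (perturbagens x
#'   features Z-score matrix), `perturbagen_meta` (data.frame with `id`,
#'   `type`, and any `dose`/`dead_flag` columns present), `feature_names`,
#'   and `platform`.
#' @export
normalize_zscore <- function(raw, group_by = c("auto", "plate", "global"),
                             average_replicates = TRUE) {
  stopifnot(inherits(raw, "raw_profile_table"))
  group_by <- match.arg(group_by)
  meta <- raw$well_meta
  has_plate <- "plate" %in% names(meta) && !all(is.na(meta$plate))
  if (group_by == "auto") group_by <- if (has_plate) "plate" else "global"
  if (group_by == "plate" && !has_plate)
    stop("group_by = 'plate' but metadata has no plate ids")
  grp <- if (group_by == "plate") as.character(meta$plate) else
    rep("all", nrow(meta))

  z <- raw$values
  for (g in unique(grp)) {
    idx <- which(grp == g)
    ctrl <- idx[meta$role[idx] == "control"]
    if (length(ctrl) < 2L)
      stop("normalization group '", g, "' has fewer than 2 control wells")
    cm <- colMeans(raw$values[ctrl, , drop = FALSE])
    cs <- apply(raw$values[ctrl, , drop = FALSE], 2L, stats::sd)
    flat <- cs == 0
    if (any(flat)) {
      warning("control sd is 0 for feature(s) ",
              paste(utils::head(colnames(z)[flat], 5L), collapse = ", "),
              " in group '", g, "'; Z set to 0")
      cs[flat] <- Inf  # (x - m)/Inf -> 0 for finite x
    }
    z[idx, ] <- sweep(sweep(raw$values[idx, , drop = FALSE], 2L, cm, "-"),
                      2L, cs, "/")
    if (any(flat)) z[idx, flat] <- 0
  }

  keep <- meta$role == "treatment"
  z <- z[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]

  if (average_replicates) {
    ids <- unique(meta$perturbagen)
    zz <- matrix(0, length(ids), ncol(z), dimnames = list(ids, colnames(z)))
    for (id in ids) {
      zz[id, ] <- colMeans(z[meta$perturbagen == id, , drop = FALSE])
    }
    pm <- meta[!duplicated(meta$perturbagen), , drop = FALSE]
    pm <- pm[match(ids, pm$perturbagen), , drop = FALSE]
  } else {
    if (anyDuplicated(meta$perturbagen))
      stop("duplicate perturbagen rows; set average_replicates = TRUE")
    zz <- z
    rownames(zz) <- meta$perturbagen
    pm <- meta
  }
  pmeta <- data.frame(id = pm$perturbagen,
                      type = if ("type" %in% names(pm)) pm$type else "reference",
                      stringsAsFactors = FALSE)
  for (extra in c("dose", "dead_flag"))
    if (extra %in% names(pm)) pmeta[[extra]] <- pm[[extra]]
  rownames(pmeta) <- NULL
  new_profile_matrix(zz, pmeta, raw$platform)
}

new_profile_matrix <- function(z, perturbagen_meta, platform = "unknown") {
  stopifnot(is.matrix(z), !anyNA(z))
  if (anyDuplicated(rownames(z))) stop("perturbagen ids must be unique")
  structure(list(z = z, perturbagen_meta = perturbagen_meta,
                 feature_names = colnames(z), platform = platform),
            class = "profile_matrix")
}

#' Construct a profile_matrix from an existing Z-score matrix
#'
#' For data already normalized elsewhere (or simulated).
#'
#' @param z Numeric matrix, perturbagens x features, with rownames.
#' @param type Character vector of perturbagen types (`"reference"` or
#'   `"fraction"`), recycled.
#' @param platform Platform label.
#' @return A `profile_matrix`.
#' @export
profile_matrix <- function(z, type = "reference", platform = "unknown") {
  if (is.null(rownames(z))) rownames(z) <- paste0("p", seq_len(nrow(z)))
  meta <- data.frame(id = rownames(z),
                     type = rep_len(type, nrow(z)),
                     stringsAsFactors = FALSE)
  new_profile_matrix(as.matrix(z), meta, platform)
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %s: %d perturbagens x %d features (%d fractions)\n",
              x$platform, nrow(x$z), ncol(x$z),
              sum(x$perturbagen_meta$type == "fraction")))
  invisible(x)
}

#' Flag "quiet" perturbagens
#'
#' A perturbagen is quiet when every Z-scored feature lies strictly inside
#' the band `(-tau, tau)`, i.e. `max |Z| < tau`.
#'
#' @param profile A `profile_matrix`.
#' @param tau Positive threshold on |Z| (default 0.5).
#' @return Named logical vector, one entry per perturbagen.
#' @seealso [quiet_summary()] for cross-platform intersection/union counts.
#' @export
flag_quiet <- function(profile, tau = 0.5) {
  stopifnot(inherits(profile, "profile_matrix"))
  if (tau <= 0) stop("tau must be > 0")
  apply(abs(profile$z), 1L, max) < tau
}

#' Summarize quiet flags across two platforms
#'
#' @param flags_a,flags_b Named logical vectors from [flag_quiet()]; ids are
#'   intersected.
#' @return List with per-platform counts and the intersection / union counts
#'   over the shared ids.
#' @export
quiet_summary <- function(flags_a, flags_b) {
  ids <- intersect(names(flags_a), names(flags_b))
  a <- flags_a[ids]; b <- flags_b[ids]
  list(n = length(ids),
       quiet_a = sum(a), quiet_b = sum(b),
       quiet_both = sum(a & b), quiet_either = sum(a | b),
       ids_both = ids[a & b])
}

#' Read a compound -> target-class annotation table
#'
#' @param path CSV with columns `id` and `target_class`; empty or missing
#'   class labels are replaced by `"none"`.
#' @param sep Field delimiter.
#' @return Data frame with columns `id`, `target_class` (class
#'   `annotation_table`).
#' @export
read_annotation_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  ann <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("id", "target_class") %in% names(ann)))
    stop("annotation table needs columns 'id' and 'target_class'")
  annotation_table(ann$id, ann$target_class)
}

#' Build an annotation table from vectors
#'
#' @param id Compound ids.
#' @param target_class Class labels; `NA` or `""` become `"none"`.
#' @return Data frame of class `annotation_table`.
#' @export
annotation_table <- function(id, target_class) {
  target_class <- as.character(target_class)
  target_class[is.na(target_class) | target_class == ""] <- "none"
  out <- data.frame(id = as.character(id), target_class = target_class,
                    stringsAsFactors = FALSE)
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' Target classes with at least `min_size` members
#'
#' Filters the annotation table to classes (excluding the explicit `"none"`
#' label) with at least `min_size` members.
#'
#' @param annotations An `annotation_table`.
#' @param min_size Minimum class size (default 5).
#' @return List with `classes` (named list class -> member ids, only classes
#'   passing the filter), `n_total_classes` (count of annotated classes
#'   before filtering), and `sizes` (named integer vector, all classes).
#' @export
class_membership <- function(annotations, min_size = 5L) {
  ann <- annotations[annotations$target_class != "none", , drop = FALSE]
  members <- split(ann$id, ann$target_class)
  sizes <- vapply(members, length, integer(1L))
  keep <- members[sizes >= min_size]
  list(classes = keep,
       n_total_classes = length(members),
       sizes = sizes)
}
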