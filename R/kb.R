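#' Construct a symptom-disease knowledge base from its five tables
#'
#' Assembles the relational knowledge base used by every inference engine:
#' symptom records carrying the owner-facing observed part (1..16),
#' disease records carrying the clinical appeared part (1..12), the
#' disease-symptom association table, the two part vocabularies, and the
#' observed-to-appeared part map that links the owner's vocabulary to the
#' clinical one. A binary disease x symptom incidence matrix and the
#' derived profile matrices needed by the engines are built on
#' construction.
#'
#' @param symptoms Data frame with columns `symptom_id`, `description`,
#'   `observed_part`.
#' @param diseases Data frame with columns `disease_id`, `description`,
#'   `appeared_part`.
#' @param associations Data frame with columns `id`, `disease_id`,
#'   `symptom_id`.
#' @param observed_parts,appeared_parts Vocabulary data frames with columns
#'   `part_id`, `label`.
#' @param part_map Data frame with columns `observed_part`,
#'   `appeared_part`: every observed part maps to exactly one appeared
#'   part.
#' @param check If `TRUE` (default) the base is validated and construction
#'   aborts on any violation.
#'
#' @return An object of class `knowledge_base`.
#' @seealso [load_kb()], [validate_kb()], [generate_kb()]
#' @export
knowledge_base <- function(symptoms, diseases, associations,
                           observed_parts, appeared_parts, part_map,
                           check = TRUE) {
  kb <- structure(list(
    symptoms = .as_table(symptoms, c("symptom_id", "description", "observed_part")),
    diseases = .as_table(diseases, c("disease_id", "description", "appeared_part")),
    associations = .as_table(associations, c("id", "disease_id", "symptom_id")),
    observed_parts = .as_table(observed_parts, c("part_id", "label")),
    appeared_parts = .as_table(appeared_parts, c("part_id", "label")),
    part_map = .as_table(part_map, c("observed_part", "appeared_part"))
  ), class = "knowledge_base")
  if (check) {
    v <- validate_kb(kb)
    if (nrow(v) > 0L)
      stop("invalid knowledge base:\n",
           paste(sprintf("  [%s row %s] %s: %s", v$table, v$row, v$rule, v$detail),
                 collapse = "\n"), call. = FALSE)
  }
  .kb_finalize(kb)
}

.as_table <- function(x, cols) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0L)
    stop("table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  x <- x[, cols, drop = FALSE]
  for (nm in cols)
    if (nm != "description" && nm != "label") x[[nm]] <- as.integer(x[[nm]])
  rownames(x) <- NULL
  x
}

# Derived quantities every engine needs: incidence matrix, per-disease
# symptom counts, L1/L2-normalized profiles, symptom co-occurrence between
# diseases, and the prototype distance scale for possibilistic typicality.
.kb_finalize <- function(kb) {
  ns <- nrow(kb$symptoms); nd <- nrow(kb$diseases)
  inc <- matrix(0, nd, ns,
                dimnames = list(as.character(kb$diseases$disease_id),
                                as.character(kb$symptoms$symptom_id)))
  if (nrow(kb$associations) > 0L) {
    di <- match(kb$associations$disease_id, kb$diseases$disease_id)
    si <- match(kb$associations$symptom_id, kb$symptoms$symptom_id)
    inc[cbind(di, si)] <- 1
  }
  kb$incidence <- inc
  nsym <- rowSums(inc)
  prof1 <- inc / pmax(nsym, 1)
  l2 <- sqrt(rowSums(inc))
  prof2 <- inc / pmax(l2, 1)
  co <- tcrossprod(inc)
  g <- tcrossprod(prof2)
  d2 <- outer(diag(g), diag(g), "+") - 2 * g
  off <- d2[upper.tri(d2)]
  kb$derived <- list(
    n_symptoms_per_disease = nsym,
    profiles_l1 = prof1,
    profiles_l2 = prof2,
    co_occurrence = co,
    proto_gamma = if (length(off) > 0L && mean(off) > 0) mean(off) else 1
  )
  # appeared part image of each observed part, indexed by observed part id
  pm <- integer(max(kb$part_map$observed_part))
  pm[kb$part_map$observed_part] <- kb$part_map$appeared_part
  kb$derived$part_image <- pm
  kb
}

#' Validate a knowledge base against its relational invariants
#'
#' Checks id uniqueness, foreign-key resolution, part-vocabulary
#' membership, association-pair uniqueness and part-map totality.
#' Violations are returned as data, not raised.
#'
#' @param kb A `knowledge_base` (finalized or a bare table list).
#' @return A data frame with columns `table`, `row`, `rule`, `detail`; zero
#'   rows iff the base is valid.
#' @export
validate_kb <- function(kb) {
  v <- list()
  add <- function(table, row, rule, detail)
    v[[length(v) + 1L]] <<- data.frame(table = table, row = row, rule = rule,
                                       detail = detail, stringsAsFactors = FALSE)
  dup <- function(ids) ids[duplicated(ids)]
  for (d in dup(kb$symptoms$symptom_id))
    add("symptoms", d, "duplicate id", sprintf("symptom_id %d occurs more than once", d))
  for (d in dup(kb$diseases$disease_id))
    add("diseases", d, "duplicate id", sprintf("disease_id %d occurs more than once", d))
  bad <- which(!(kb$symptoms$observed_part %in% kb$observed_parts$part_id))
  for (i in bad)
    add("symptoms", kb$symptoms$symptom_id[i], "unknown part",
        sprintf("observed_part %d not in ObservedPart vocabulary",
                kb$symptoms$observed_part[i]))
  bad <- which(!(kb$diseases$appeared_part %in% kb$appeared_parts$part_id))
  for (i in bad)
    add("diseases", kb$diseases$disease_id[i], "unknown part",
        sprintf("appeared_part %d not in AppearedPart vocabulary",
                kb$diseases$appeared_part[i]))
  a <- kb$associations
  bad <- which(!(a$disease_id %in% kb$diseases$disease_id))
  for (i in bad)
    add("associations", a$id[i], "dangling foreign key",
        sprintf("disease_id %d not found", a$disease_id[i]))
  bad <- which(!(a$symptom_id %in% kb$symptoms$symptom_id))
  for (i in bad)
    add("associations", a$id[i], "dangling foreign key",
        sprintf("symptom_id %d not found", a$symptom_id[i]))
  key <- paste(a$disease_id, a$symptom_id)
  for (i in which(duplicated(key)))
    add("associations", a$id[i], "duplicate pair",
        sprintf("(disease %d, symptom %d) repeated", a$disease_id[i], a$symptom_id[i]))
  pm <- kb$part_map
  for (d in dup(pm$observed_part))
    add("part_map", d, "duplicate id",
        sprintf("observed_part %d mapped more than once", d))
  bad <- which(!(pm$observed_part %in% kb$observed_parts$part_id))
  for (i in bad)
    add("part_map", pm$observed_part[i], "unknown part",
        sprintf("observed_part %d not in vocabulary", pm$observed_part[i]))
  bad <- which(!(pm$appeared_part %in% kb$appeared_parts$part_id))
  for (i in bad)
    add("part_map", pm$observed_part[i], "unknown part",
        sprintf("appeared_part %d not in vocabulary", pm$appeared_part[i]))
  unmapped <- setdiff(kb$observed_parts$part_id, pm$observed_part)
  for (d in unmapped)
    add("part_map", d, "missing mapping",
        sprintf("observed_part %d has no appeared_part image", d))
  if (length(v) == 0L)
    return(data.frame(table = character(), row = integer(), rule = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

.kb_tables <- c("symptoms", "diseases", "associations",
                "observed_parts", "appeared_parts", "part_map")

#' Load a knowledge base from disk
#'
#' Reads the six tables (five relational tables plus the
#' observed-to-appeared part map) from either a directory of CSV files
#' (the canonical format) or a single JSON file, validates them and builds
#' the incidence matrix.
#'
#' @param path Directory (csv) or file (json) to read.
#' @param format `"csv"` or `"json"`; default guesses from `path`.
#' @return A validated `knowledge_base`.
#' @export
load_kb <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "csv" else "json"
  if (format == "csv") {
    tabs <- lapply(.kb_tables, function(tb) {
      f <- file.path(path, paste0(tb, ".csv"))
      if (!file.exists(f))
        stop(sprintf("missing table '%s': expected file %s", tb, f), call. = FALSE)
      utils::read.csv(f, stringsAsFactors = FALSE)
    })
  } else {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    missing <- setdiff(.kb_tables, names(obj))
    if (length(missing) > 0L)
      stop("missing table(s) in JSON: ", paste(missing, collapse = ", "),
           call. = FALSE)
    tabs <- lapply(.kb_tables, function(tb) as.data.frame(obj[[tb]]))
  }
  names(tabs) <- .kb_tables
  knowledge_base(tabs$symptoms, tabs$diseases, tabs$associations,
                 tabs$observed_parts, tabs$appeared_parts, tabs$part_map)
}

#' Write a knowledge base to disk
#'
#' Inverse of [load_kb()]: emits the six tables either as UTF-8 CSV files
#' with header rows inside `path` (created if needed) or as one JSON file.
#'
#' @param kb A `knowledge_base`.
#' @param path Target directory (csv) or file (json).
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (tb in .kb_tables)
      utils::write.csv(kb[[tb]], file.path(path, paste0(tb, ".csv")),
                       row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(kb[.kb_tables], path, dataframe = "columns",
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Diseases eligible as benchmark targets
#'
#' Returns, in ascending id order, the diseases whose number of associated
#' symptoms is at least `min_symptoms` (default 5, matching the benchmark's
#' requirement that a target supports a five-symptom query).
#'
#' @param kb A `knowledge_base`.
#' @param min_symptoms Minimum registered symptom count (>= 1).
#' @return Integer vector of disease ids.
#' @export
eligible_targets <- function(kb, min_symptoms = 5L) {
  if (min_symptoms < 1) stop("'min_symptoms' must be >= 1", call. = FALSE)
  ids <- kb$diseases$disease_id[kb$derived$n_symptoms_per_disease >= min_symptoms]
  sort(ids)
}

#' Per-symptom count statistics
#'
#' For one symptom: the number of diseases that carry it and the number of
#' distinct appeared parts among those diseases. These are the raw counts
#' behind the symptom-relevance coordinates.
#'
#' @param kb A `knowledge_base`.
#' @param symptom_id A registered symptom id.
#' @return Named integer vector `c(n_diseases =, n_parts =)`.
#' @export
symptom_stats <- function(kb, symptom_id) {
  si <- match(symptom_id, kb$symptoms$symptom_id)
  if (is.na(si)) stop("unknown symptom_id: ", symptom_id, call. = FALSE)
  has <- kb$incidence[, si] > 0
  c(n_diseases = sum(has),
    n_parts = length(unique(kb$diseases$appeared_part[has])))
}

#' Build a query from symptom ids
#'
#' A query is the owner's input: an ordered list of (observed part,
#' symptom) pairs. This helper looks up each symptom's registered observed
#' part.
#'
#' @param kb A `knowledge_base`.
#' @param symptom_ids Vector of registered symptom ids, no duplicates,
#'   length 1..20.
#' @return A data frame with columns `observed_part`, `symptom_id` of class
#'   `prediag_query`.
#' @export
query_from_symptoms <- function(kb, symptom_ids) {
  si <- match(symptom_ids, kb$symptoms$symptom_id)
  if (anyNA(si))
    stop("unknown symptom_id: ",
         paste(symptom_ids[is.na(si)], collapse = ", "), call. = FALSE)
  q <- data.frame(observed_part = kb$symptoms$observed_part[si],
                  symptom_id = as.integer(symptom_ids))
  class(q) <- c("prediag_query", "data.frame")
  validate_query(kb, q)
  q
}

#' Validate a query against a knowledge base
#'
#' Checks that the query is non-empty (length 1..20), has no duplicate
#' symptoms, that every symptom exists, and that each stated observed part
#' agrees with the symptom's registered part.
#'
#' @param kb A `knowledge_base`.
#' @param query A data frame with columns `observed_part`, `symptom_id`.
#' @return The query, invisibly; errors on violation.
#' @export
validate_query <- function(kb, query) {
  if (!all(c("observed_part", "symptom_id") %in% names(query)))
    stop("query needs columns 'observed_part' and 'symptom_id'", call. = FALSE)
  n <- nrow(query)
  if (n < 1L || n > 20L)
    stop("query must contain between 1 and 20 symptoms", call. = FALSE)
  if (anyDuplicated(query$symptom_id))
    stop("query contains duplicate symptom ids", call. = FALSE)
  si <- match(query$symptom_id, kb$symptoms$symptom_id)
  if (anyNA(si))
    stop("unknown symptom_id: ",
         paste(query$symptom_id[is.na(si)], collapse = ", "), call. = FALSE)
  reg <- kb$symptoms$observed_part[si]
  bad <- which(reg != query$observed_part)
  if (length(bad) > 0L)
    stop("observed_part mismatch for symptom(s): ",
         paste(query$symptom_id[bad], collapse = ", "), call. = FALSE)
  invisible(query)
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf(
    "Symptom-disease knowledge base: %d symptoms (%d observed parts), %d diseases (%d appeared parts), %d associations\n",
    nrow(x$symptoms), nrow(x$observed_parts), nrow(x$diseases),
    nrow(x$appeared_parts), nrow(x$associations)))
  cat(sprintf("Eligible targets (>= 5 symptoms): %d\n",
              length(eligible_targets(x))))
  invisible(x)
}
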