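# Readers and writers for the plain-text formats the toolkit touches:
# protein FASTA, secondary-structure tracks (PSIPRED .ss2 or a FASTA-like
# states dialect), feature-annotation TSV, group-membership TSV, and the
# key = value reference-anchor config.

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased, a single terminal `*` (stop) is stripped, and
#' every residue must belong to the 20-letter amino-acid alphabet plus `X`.
#' The record id is the first whitespace-delimited token of the header; the
#' remainder becomes the description. Duplicate ids are rejected.
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `id`, `description`, `sequence`,
#'   `species` (NA), `group` (NA).
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0) stop("FASTA parse error: no records in ", path, call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  if (any(!nzchar(seqs))) {
    stop("record '", ids[which(!nzchar(seqs))[1]], "': empty sequence", call. = FALSE)
  }
  for (i in seq_along(seqs)) validate_residues(seqs[i], ids[i])
  protein_records(id = ids, description = desc, sequence = seqs)
}

#' Construct a validated protein record collection
#'
#' @param id,sequence character vectors of equal length.
#' @param description,species,group optional metadata vectors.
#' @return data.frame with one row per protein.
#' @export
protein_records <- function(id, sequence, description = "",
                            species = NA_character_, group = NA_character_) {
  stopifnot(length(id) == length(sequence))
  if (anyDuplicated(id)) stop("duplicate record id(s)", call. = FALSE)
  sequence <- toupper(sequence)
  if (any(!nzchar(sequence))) stop("empty sequence", call. = FALSE)
  for (i in seq_along(sequence)) validate_residues(sequence[i], id[i])
  data.frame(id = as.character(id),
             description = rep_len(as.character(description), length(id)),
             sequence = sequence,
             species = rep_len(as.character(species), length(id)),
             group = rep_len(as.character(group), length(id)),
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records data.frame as returned by [read_protein_fasta()].
#' @param path output path.
#' @export
write_protein_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- ifelse(nzchar(records$description),
                       paste(records$id, records$description),
                       records$id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read per-residue secondary-structure tracks
#'
#' Two dialects are supported. `"states"` is a FASTA-like pairing of an id
#' header and an H/E/C state string. `"ss2"` is the PSIPRED vertical format
#' (columns: position, residue, state, three probabilities); one protein per
#' file, with `protein_id` taken from the file name unless given. E and C
#' are both treated as non-helical downstream.
#'
#' @param path input file.
#' @param dialect `"states"` or `"ss2"`.
#' @param protein_id id to assign for the ss2 dialect (default: file stem).
#' @return data.frame with columns `protein_id`, `states`.
#' @export
read_ss_track <- function(path, dialect = c("states", "ss2"),
                          protein_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("track file not found: ", path, call. = FALSE)
  if (dialect == "states") {
    set <- tryCatch(
      Biostrings::readBStringSet(path),
      error = function(e) stop("states parse error in '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    )
    ids <- sub("\\s.*$", "", names(set))
    states <- toupper(as.character(set))
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    if (length(lines) == 0) stop("ss2 parse error: no data rows in ", path, call. = FALSE)
    fields <- strsplit(trimws(lines), "\\s+")
    nf <- lengths(fields)
    if (any(nf < 3)) {
      stop(sprintf("ss2 parse error in '%s': line %d has %d fields (need >= 3)",
                   path, which(nf < 3)[1], nf[which(nf < 3)[1]]), call. = FALSE)
    }
    states <- paste(vapply(fields, `[[`, "", 3L), collapse = "")
    ids <- if (is.null(protein_id)) tools::file_path_sans_ext(basename(path)) else protein_id
  }
  for (i in seq_along(states)) {
    chars <- seq_chars(states[i])
    bad <- which(!chars %in% c("H", "E", "C"))
    if (length(bad) > 0) {
      stop(sprintf("track '%s': unknown state symbol '%s' at position %d",
                   ids[i], chars[bad[1]], bad[1]), call. = FALSE)
    }
  }
  data.frame(protein_id = ids, states = states, stringsAsFactors = FALSE)
}

#' Read a coiled-coil / transmembrane annotation table
#'
#' TSV with header `protein_id`, `feature`, `start`, `end`; coordinates are
#' 1-based inclusive. Feature codes are restricted to `CC` and `TM`.
#' Overlapping spans for one protein are permitted.
#'
#' @param path input TSV.
#' @return data.frame with the four columns above.
#' @export
read_annotation_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "feature", "start", "end")
  if (!all(need %in% names(tab))) {
    stop("annotation table must have header: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tab) == 0) {
    return(data.frame(protein_id = character(), feature = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  bad_feat <- which(!tab$feature %in% c("CC", "TM"))
  if (length(bad_feat) > 0) {
    stop("unknown feature code '", tab$feature[bad_feat[1]], "' in row ",
         bad_feat[1], call. = FALSE)
  }
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  bad <- which(is.na(tab$start) | is.na(tab$end) |
                 tab$start < 1 | tab$start > tab$end)
  if (length(bad) > 0) {
    stop(sprintf("invalid span in row %d: start=%s end=%s",
                 bad[1], tab$start[bad[1]], tab$end[bad[1]]), call. = FALSE)
  }
  tab[, need]
}

#' Write an annotation table
#' @param annotations data.frame as from [read_annotation_table()].
#' @param path output TSV path.
#' @export
write_annotation_table <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a protein-to-group membership table
#'
#' TSV with header `protein_id`, `group`. Group labels follow the septin
#' clade vocabulary (1A, 1B, 2, 3, 4, 5, 6A, 6B, 7, 8, orphan) but any
#' label is accepted.
#'
#' @param path input TSV.
#' @return named character vector mapping protein_id to group.
#' @export
read_group_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "group") %in% names(tab))) {
    stop("group table must have header: protein_id, group", call. = FALSE)
  }
  stats::setNames(as.character(tab$group), tab$protein_id)
}

#' Read a reference-anchor config file
#'
#' A flat `key = value` file defining the reference record and its anchor
#' coordinates. Recognised keys: `reference_fasta` (path, resolved relative
#' to the config file), `gtpase_start`, `gtpase_end`, `r_finger_col`,
#' `switch1_col`, `coverage_floor`, `gap_open`, `gap_extend`. Missing
#' numeric keys fall back to the defaults of [reference_anchor()].
#'
#' @param path config file path.
#' @return a `reference_anchor` object.
#' @export
read_anchor_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*?)\\s*$", lines))
  bad <- which(lengths(kv) != 3)
  if (length(bad) > 0) {
    stop("config parse error at line: ", lines[bad[1]], call. = FALSE)
  }
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- vapply(kv, `[[`, "", 3L)
  conf <- stats::setNames(as.list(vals), keys)
  if (is.null(conf$reference_fasta)) {
    stop("config error: reference_fasta is required", call. = FALSE)
  }
  ref_path <- conf$reference_fasta
  if (!file.exists(ref_path)) {
    ref_path <- file.path(dirname(path), conf$reference_fasta)
  }
  ref <- read_protein_fasta(ref_path)
  num <- function(key, default) {
    if (is.null(conf[[key]])) default else as.numeric(conf[[key]])
  }
  reference_anchor(
    reference = ref[1, , drop = FALSE],
    gtpase_start = as.integer(num("gtpase_start", NA)),
    gtpase_end = as.integer(num("gtpase_end", NA)),
    r_finger_col = as.integer(num("r_finger_col", NA)),
    switch1_col = as.integer(num("switch1_col", NA)),
    coverage_floor = num("coverage_floor", 0.5),
    gap_open = num("gap_open", 10),
    gap_extend = num("gap_extend", 1)
  )
}
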