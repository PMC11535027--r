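#' Default column schema for probe tables
#'
#' Probe tables are plain delimited files with one row per (probe, condition).
#' The schema maps the package's canonical column names to the names actually
#' present in a file, so differently labelled exports can be read without
#' renaming on disk.
#'
#' @param ... Named overrides, e.g. `residue = "resid"` if the file calls the
#'   residue-number column `resid`.
#' @return Named character vector mapping canonical names to file column names.
#' @export
#' @examples
#' default_schema()
#' default_schema(residue = "resid", intensity = "height")
default_schema <- function(...) {
  schema <- c(
    residue = "residue", residue_type = "residue_type", atom = "atom",
    stereo = "stereo", delay_s = "delay_s", nu_cpmg_Hz = "nu_cpmg_Hz",
    intensity = "intensity", sigma = "sigma", field_T = "field_T",
    experiment = "experiment", nucleus = "nucleus", shift_ppm = "shift_ppm"
  )
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(schema))
    if (length(bad)) {
      abort(paste0("Unknown schema field(s): ", paste(bad, collapse = ", ")))
    }
    schema[names(over)] <- over
  }
  schema
}

# Closed vocabulary of probe atom labels.  Backbone amides plus the
# methyl-bearing side-chain positions of an ILVMAT-type labelling scheme.
.atom_vocab <- c(
  "N-H",
  "Ile-d1", "Leu-d1", "Leu-d2", "Val-g1", "Val-g2",
  "Met-e", "Ala-b", "Thr-g2"
)

#' Probe atom-label vocabulary
#'
#' @return Character vector of accepted `atom` labels: the backbone amide
#'   (`"N-H"`) and the methyl positions of Ile, Leu, Val, Met, Ala and Thr.
#' @export
probe_atom_vocabulary <- function() .atom_vocab

#' Read a probe-keyed table from a delimited file
#'
#' Reads a CSV or TSV file (delimiter auto-detected from the header line),
#' validates it against a column schema, and returns a tibble with canonical
#' column names. Rows whose declared-numeric fields fail to parse are rejected
#' with their line numbers; duplicated probe keys raise an integrity error.
#'
#' @param path Path to a UTF-8 CSV/TSV file with a header row.
#' @param schema Column mapping from [default_schema()]. Only columns named in
#'   `required` must be present.
#' @param required Canonical names of columns that must exist in the file.
#' @param numeric_cols Canonical names of columns that must parse as numeric.
#'   Defaults to the intersection of the file's columns with the schema's
#'   known numeric fields.
#' @param key_cols Canonical columns whose combination must be unique; set to
#'   `NULL` to skip the uniqueness check (e.g. long-format decay tables).
#' @return A tibble with canonical column names.
#' @export
read_probe_table <- function(path, schema = default_schema(),
                             required = c("residue", "atom"),
                             numeric_cols = NULL,
                             key_cols = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  missing_cols <- required[!schema[required] %in% names(raw)]
  if (length(missing_cols)) {
    abort(paste0("Schema error: missing column(s): ",
                 paste(schema[missing_cols], collapse = ", ")))
  }
  present <- names(schema)[schema %in% names(raw)]
  out <- raw
  names(out)[match(schema[present], names(raw))] <- present

  known_numeric <- c("residue", "delay_s", "nu_cpmg_Hz", "intensity",
                     "sigma", "field_T", "shift_ppm")
  numeric_cols <- numeric_cols %||% intersect(present, known_numeric)
  bad_rows <- integer(0)
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(vals) & !is.na(out[[col]]) & out[[col]] != "")
    bad_rows <- union(bad_rows, bad)
    out[[col]] <- vals
  }
  if (length(bad_rows)) {
    # +1 converts data-row index to file line number (header is line 1)
    abort(paste0("Unparseable numeric value(s) at file line(s): ",
                 paste(sort(bad_rows) + 1L, collapse = ", ")))
  }
  if (!is.null(key_cols)) {
    keys <- do.call(paste, c(out[key_cols], sep = "\r"))
    if (anyDuplicated(keys)) {
      abort(paste0("Integrity error: duplicated probe key(s): ",
                   paste(unique(gsub("\r", "/", keys[duplicated(keys)])),
                         collapse = "; ")))
    }
  }
  as_tibble(out)
}

#' Write a results table to CSV
#'
#' Numeric fields are written at full precision (15 significant digits) so a
#' write/read round trip reproduces them to better than 1e-12 relative.
#'
#' @param x A data frame of results.
#' @param path Output file path.
#' @return `x`, invisibly.
#' @export
write_results <- function(x, path) {
  stopifnot(is.data.frame(x))
  out <- x
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
    }
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(x)
}

#' Extract per-residue bond unit vectors from a PDB structure
#'
#' For amide probes the vector is N to H; amide protons missing from an X-ray
#' model are optionally reconstructed at 1.02 angstrom opposite the bisector
#' of the N-CA and N-C(i-1) directions (i.e. in the peptide plane, trans to
#' the carbonyl). For methyl probes the vector is the parent carbon to the
#' methyl carbon (the methyl symmetry axis).
#'
#' @param pdb_path Path to a PDB file.
#' @param pair Either `"amide"` (N->H) or `"methyl"` (Cparent->Cmethyl).
#' @param model Model index for multi-model files (default 1; bio3d reads the
#'   first model by default).
#' @param reconstruct_H Reconstruct missing amide protons from backbone
#'   geometry (default `TRUE`). Residues that still lack atoms are reported in
#'   the `skipped` attribute.
#' @return A tibble with columns `residue`, `residue_type`, `atom`, `x`, `y`,
#'   `z` (unit vector components) and `source`; skipped residues in
#'   `attr(, "skipped")`.
#' @export
extract_bond_vectors <- function(pdb_path, pair = c("amide", "methyl"),
                                 model = 1, reconstruct_H = TRUE) {
  pair <- match.arg(pair)
  pdb <- tryCatch(bio3d::read.pdb(pdb_path, verbose = FALSE),
                  error = function(e) abort(paste0("Unreadable PDB file: ", pdb_path,
                                                   " (", conditionMessage(e), ")")))
  at <- as_tibble(pdb$atom)
  at <- filter(at, .data$type == "ATOM")
  if (pair == "amide") {
    res <- .amide_vectors(at, reconstruct_H)
  } else {
    res <- .methyl_vectors(at)
  }
  if (is.null(res$vectors) || nrow(res$vectors) == 0) {
    empty <- tibble(residue = integer(0), residue_type = character(0),
                    atom = character(0), x = numeric(0), y = numeric(0),
                    z = numeric(0), source = character(0))
    return(structure(empty, skipped = res$skipped))
  }
  res$vectors$source <- paste0(basename(pdb_path), "#", model)
  nrm <- with(res$vectors, sqrt(x^2 + y^2 + z^2))
  if (any(abs(nrm - 1) > 1e-6)) abort("Geometry error: non-unit bond vector produced")
  structure(res$vectors, skipped = res$skipped)
}

.get_xyz <- function(at, resno, name) {
  row <- at[at$resno == resno & at$elety == name, , drop = FALSE]
  if (nrow(row) < 1) return(NULL)
  c(row$x[1], row$y[1], row$z[1])
}

.unitv <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) abort("Geometry error: zero-length bond vector")
  v / n
}

.amide_vectors <- function(at, reconstruct_H) {
  resnos <- sort(unique(at$resno))
  rows <- list(); skipped <- character(0)
  for (r in resnos) {
    n_xyz <- .get_xyz(at, r, "N")
    if (is.null(n_xyz)) { skipped <- c(skipped, paste0(r, ": no N")); next }
    h_xyz <- .get_xyz(at, r, "H") %||% .get_xyz(at, r, "HN")
    if (is.null(h_xyz)) {
      if (!reconstruct_H) { skipped <- c(skipped, paste0(r, ": no H")); next }
      ca <- .get_xyz(at, r, "CA")
      cprev <- .get_xyz(at, r - 1, "C")
      if (is.null(ca) || is.null(cprev)) {
        skipped <- c(skipped, paste0(r, ": H not reconstructible")); next
      }
      bis <- .unitv(.unitv(ca - n_xyz) + .unitv(cprev - n_xyz))
      h_xyz <- n_xyz - 1.02 * bis
    }
    u <- .unitv(h_xyz - n_xyz)
    rt <- at$resid[at$resno == r][1]
    rows[[length(rows) + 1L]] <- tibble(
      residue = r, residue_type = rt, atom = "N-H",
      x = u[1], y = u[2], z = u[3]
    )
  }
  list(vectors = list_rbind(rows), skipped = skipped)
}

# methyl carbon -> (parent carbon, atom label)
.methyl_map <- list(
  ILE = list(c("CD1", "CG1", "Ile-d1")),
  LEU = list(c("CD1", "CG", "Leu-d1"), c("CD2", "CG", "Leu-d2")),
  VAL = list(c("CG1", "CB", "Val-g1"), c("CG2", "CB", "Val-g2")),
  MET = list(c("CE", "SD", "Met-e")),
  ALA = list(c("CB", "CA", "Ala-b")),
  THR = list(c("CG2", "CB", "Thr-g2"))
)

.methyl_vectors <- function(at) {
  rows <- list(); skipped <- character(0)
  resnos <- sort(unique(at$resno))
  for (r in resnos) {
    rt <- at$resid[at$resno == r][1]
    specs <- .methyl_map[[rt]]
    if (is.null(specs)) next
    for (sp in specs) {
      me <- .get_xyz(at, r, sp[1]); parent <- .get_xyz(at, r, sp[2])
      if (is.null(me) || is.null(parent)) {
        skipped <- c(skipped, paste0(r, " ", sp[3], ": atoms missing")); next
      }
      u <- .unitv(me - parent)
      rows[[length(rows) + 1L]] <- tibble(
        residue = r, residue_type = rt, atom = sp[3],
        x = u[1], y = u[2], z = u[3]
      )
    }
  }
  list(vectors = list_rbind(rows), skipped = skipped)
}
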