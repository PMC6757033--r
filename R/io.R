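# File formats: XYZ geometry, MOL/SDF V2000 (geometry + bonds), plain-text
# torsion specs, and YAML run configuration. Atom indices are 1-based both
# in files and internally; angles are degrees in files, radians internally.

#' Read an XYZ geometry file
#'
#' Standard format: atom count line, comment line, then `element x y z`
#' rows (Å).
#'
#' @param path file path.
#' @return List with `elements`, `coords` (n x 3 matrix), `comment`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("malformed XYZ: fewer than two lines")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n)) stop("malformed XYZ: line 1 is not an atom count")
  if (length(lines) < 2L + n)
    stop(sprintf("malformed XYZ: expected %d atom lines, found %d", n, length(lines) - 2L))
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[2L + i]), "\\s+")[[1L]]
    if (length(parts) < 4L)
      stop(sprintf("malformed XYZ: line %d has fewer than 4 fields", 2L + i))
    xyz <- suppressWarnings(as.numeric(parts[2:4]))
    if (anyNA(xyz))
      stop(sprintf("malformed XYZ: line %d has non-numeric coordinates", 2L + i))
    elements[i] <- parts[1L]
    coords[i, ] <- xyz
  }
  list(elements = elements, coords = coords, comment = lines[2L])
}

#' Write an XYZ geometry file
#'
#' @param elements element symbols.
#' @param coords n x 3 coordinate matrix (Å).
#' @param path output path.
#' @param comment comment line.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(elements, coords, path, comment = "") {
  lines <- c(as.character(length(elements)), comment,
             sprintf("%s %.10f %.10f %.10f", elements,
                     coords[, 1], coords[, 2], coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a MOL/SDF V2000 block
#'
#' Parses the counts line, atom block (element + coordinates), and bond
#' block of a V2000 MOL file. Charge/isotope fields are ignored with a
#' warning when nonzero. Torsions are supplied separately
#' ([read_torsion_spec()]).
#'
#' @param path file path.
#' @return List with `elements`, `coords`, `bonds` (2-column matrix).
#' @export
read_sdf <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L) stop("malformed MOL: fewer than 4 lines")
  counts <- lines[4L]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || is.na(n_bonds)) stop("malformed MOL: bad counts line")
  if (length(lines) < 4L + n_atoms + n_bonds)
    stop("malformed MOL: counts line does not match file length")
  if (n_atoms > 1L && n_bonds == 0L)
    stop("malformed MOL: multi-atom system with empty bond block")
  elements <- character(n_atoms)
  coords <- matrix(NA_real_, n_atoms, 3)
  saw_charge <- FALSE
  for (i in seq_len(n_atoms)) {
    ln <- lines[4L + i]
    coords[i, ] <- as.numeric(c(substr(ln, 1, 10), substr(ln, 11, 20),
                                substr(ln, 21, 30)))
    elements[i] <- trimws(substr(ln, 32, 34))
    chg <- suppressWarnings(as.integer(substr(ln, 37, 39)))
    if (!is.na(chg) && chg != 0L) saw_charge <- TRUE
  }
  if (anyNA(coords)) stop("malformed MOL: non-numeric atom coordinates")
  if (saw_charge) warning("charge/isotope fields in MOL atom block ignored")
  bonds <- matrix(NA_integer_, n_bonds, 2)
  for (i in seq_len(n_bonds)) {
    ln <- lines[4L + n_atoms + i]
    bonds[i, ] <- as.integer(c(substr(ln, 1, 3), substr(ln, 4, 6)))
  }
  if (anyNA(bonds)) stop("malformed MOL: bad bond block")
  list(elements = elements, coords = coords, bonds = bonds)
}

#' Read a torsion-spec file
#'
#' Plain text listing one rotatable bond per line as two 1-based atom
#' indices; `#` starts a comment. Order defines the torsion indexing.
#'
#' @param path file path.
#' @return Integer matrix with two columns.
#' @export
read_torsion_spec <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("torsion spec contains no bonds")
  rows <- lapply(seq_along(lines), function(i) {
    parts <- suppressWarnings(as.integer(strsplit(lines[i], "\\s+")[[1L]]))
    if (length(parts) != 2L || anyNA(parts))
      stop(sprintf("torsion spec line %d: expected two atom indices", i))
    parts
  })
  do.call(rbind, rows)
}

#' Write a torsion-spec file
#'
#' @param torsion_bonds 2-column integer matrix (1-based atom indices).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_torsion_spec <- function(torsion_bonds, path) {
  writeLines(c("# rotatable bonds: atom_i atom_j (1-based)",
               sprintf("%d %d", torsion_bonds[, 1], torsion_bonds[, 2])), path)
  invisible(path)
}

#' Load a run configuration from YAML
#'
#' Recognized top-level keys: the [search_config()] fields (`d`, `s`, `A`,
#' `B`, `gamma`, `penalty_floor`, `seed`, `solver`, `sa_reads`,
#' `target_energy`, `target_tol`), an `sa` section (`beta0`, `beta1`,
#' `sweeps`), and a `ptmc` section ([ptmc_config()] fields). Unknown keys
#' are an error. An empty file yields full defaults. The effective
#' parameters are echoed via `message()` for provenance.
#'
#' @param path YAML file path.
#' @param quiet suppress the provenance echo.
#' @return List with `search` (a `search_config`) and `ptmc` (a
#'   `ptmc_config`).
#' @export
load_config <- function(path, quiet = FALSE) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  search_keys <- c("d", "s", "A", "B", "gamma", "penalty_floor", "seed",
                   "solver", "sa_reads", "target_energy", "target_tol")
  known <- c(search_keys, "sa", "ptmc")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  sa_raw <- raw$sa
  if (!is.null(sa_raw)) {
    bad <- setdiff(names(sa_raw), c("beta0", "beta1", "sweeps"))
    if (length(bad)) stop(sprintf("unknown sa key(s): %s", paste(bad, collapse = ", ")))
  }
  sched <- do.call(sa_schedule, as.list(sa_raw))
  scfg <- do.call(search_config,
                  c(raw[intersect(names(raw), search_keys)],
                    list(sa_schedule = sched)))
  ptmc_raw <- raw$ptmc
  if (!is.null(ptmc_raw)) {
    bad <- setdiff(names(ptmc_raw),
                   c("n_replicas", "kT_min", "kT_max", "sweeps", "swap_every", "seed"))
    if (length(bad)) stop(sprintf("unknown ptmc key(s): %s", paste(bad, collapse = ", ")))
  }
  pcfg <- do.call(ptmc_config, as.list(ptmc_raw))
  if (!quiet) {
    message(sprintf(
      "config: d=%d s=%d A=%d B=%d gamma=%g solver=%s seed=%s | ptmc: %d replicas, kT %.3g-%.3g, %d sweeps",
      scfg$d, scfg$s, scfg$A, scfg$B, scfg$gamma, scfg$solver,
      ifelse(is.null(scfg$seed), "NULL", scfg$seed),
      pcfg$n_replicas, min(pcfg$kT), max(pcfg$kT), pcfg$sweeps))
  }
  list(search = scfg, ptmc = pcfg)
}

#' Assemble a molecular system from geometry, bond, and torsion files
#'
#' Accepts either an XYZ file plus a bond list (2-column text like the
#' torsion spec) or an SDF/MOL file, plus a torsion-spec file.
#'
#' @param geometry path to `.xyz` or `.sdf`/`.mol` file.
#' @param torsions path to a torsion-spec file.
#' @param bonds path to a bond-list file (required with XYZ input).
#' @param name molecule label.
#' @return A [molecular_system()].
#' @export
read_molecule <- function(geometry, torsions, bonds = NULL, name = NULL) {
  ext <- tolower(tools::file_ext(geometry))
  if (ext == "xyz") {
    if (is.null(bonds)) stop("XYZ input needs a bond-list file")
    geo <- read_xyz(geometry)
    bond_mat <- read_torsion_spec(bonds)  # same two-column format
  } else if (ext %in% c("sdf", "mol")) {
    geo <- read_sdf(geometry)
    bond_mat <- geo$bonds
  } else stop("unsupported geometry format: ", ext)
  molecular_system(geo$elements, geo$coords, bond_mat,
                   read_torsion_spec(torsions),
                   name = if (is.null(name)) basename(geometry) else name)
}
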