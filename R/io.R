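#' COLVAR and HILLS text files
#'
#' Whitespace-separated tables with a `#! FIELDS <names...>` header line,
#' the dialect written by common biasing engines. Numbers are written with
#' 17 significant digits, so write-then-read round trips are bit-exact.
#' Unknown columns are parsed and preserved; a malformed line (token count
#' differing from the header, e.g. a truncated final line) is an error
#' naming the line number.
#'
#' @name plumed_io
NULL

fmt_num <- function(x) {
  vapply(x, function(v)
    if (is.na(v)) "NA" else sprintf("%.17g", v), character(1))
}

#' @rdname plumed_io
#' @param records data.frame of frame records (first column conventionally
#'   `time`)
#' @param path output file
#' @export
write_colvar <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(records), collapse = " ")), con)
  if (nrow(records) > 0) {
    body <- do.call(paste, c(lapply(records, fmt_num), sep = " "))
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname plumed_io
#' @return `read_colvar`: data.frame with the header's columns
#' @export
read_colvar <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#! FIELDS"))
    stop("missing '#! FIELDS' header in ", path)
  fields <- strsplit(sub("^#! FIELDS +", "", lines[1]), "[ \t]+")[[1]]
  body <- lines[-1]
  body <- body[!startsWith(body, "#")]
  if (length(body) == 0) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(fields)), fields))
    return(out)
  }
  toks <- strsplit(trimws(body), "[ \t]+")
  nt <- lengths(toks)
  bad <- which(nt != length(fields))
  if (length(bad))
    stop(sprintf("line %d of %s has %d fields, header declares %d",
                 bad[1] + 1L, path, nt[bad[1]], length(fields)))
  m <- matrix(suppressWarnings(as.numeric(unlist(toks))),
              ncol = length(fields), byrow = TRUE)
  out <- as.data.frame(m)
  names(out) <- fields
  out
}

#' @rdname plumed_io
#' @param ledger a `hills_ledger`
#' @export
write_hills <- function(ledger, path) {
  write_colvar(ledger$records, path)
}

#' @rdname plumed_io
#' @param cv_names CV names expected in the file (defaults to every column
#'   between `time` and the first `sigma_` column)
#' @return `read_hills`: a `hills_ledger`
#' @export
read_hills <- function(path, cv_names = NULL) {
  rec <- read_colvar(path)
  if ("walker" %in% names(rec)) rec$walker <- as.integer(rec$walker)
  if (is.null(cv_names)) {
    sig <- grep("^sigma_", names(rec), value = TRUE)
    cv_names <- sub("^sigma_", "", sig)
  }
  for (w in unique(rec$walker)) {
    t_w <- rec$time[rec$walker == w]
    if (is.unsorted(t_w, strictly = FALSE) || anyDuplicated(t_w))
      warning(sprintf("non-monotone hill times for walker %s in %s", w, path))
  }
  # already-ordered files round trip unchanged; disordered input is sorted
  # into the canonical (time, walker) merge order
  rec <- rec[order(rec$time, rec$walker), , drop = FALSE]
  rownames(rec) <- NULL
  hills_ledger(cv_names, rec)
}

#' Write an XYZ trajectory
#'
#' Coordinates are converted from nm to Angstrom (the conventional XYZ
#' unit). One block per frame: atom count, comment, then element and x y z.
#'
#' @param frames list of n x 3 coordinate matrices in nm, or a single matrix
#' @param path output file
#' @param elements per-atom element symbols (recycled)
#' @param comments per-frame comment lines
#' @export
write_xyz <- function(frames, path, elements = "C", comments = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    m <- frames[[i]]
    el <- rep(elements, length.out = nrow(m))
    writeLines(as.character(nrow(m)), con)
    writeLines(if (is.null(comments)) sprintf("frame %d", i - 1L)
               else comments[i], con)
    writeLines(sprintf("%s %.10f %.10f %.10f", el,
                       nm_to_A(m[, 1]), nm_to_A(m[, 2]), nm_to_A(m[, 3])),
               con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @return `read_xyz`: list of coordinate matrices in nm with element
#'   attributes
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("bad atom count at line ", i, " of ", path)
    if (i + 1L + n > length(lines)) stop("truncated frame at line ", i)
    toks <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "[ \t]+")
    m <- matrix(as.numeric(unlist(lapply(toks, `[`, 2:4))), ncol = 3,
                byrow = TRUE)
    m <- A_to_nm(m)
    attr(m, "elements") <- vapply(toks, `[`, character(1), 1L)
    frames[[length(frames) + 1L]] <- m
    i <- i + 2L + n
  }
  frames
}

#' Write a toy complex as a minimal PDB
#'
#' Beads become atoms; receptor pseudo-residue groups become residues
#' (chain R), the ligand chain L, waters chain W (residue HOH). Coordinates
#' are written in Angstrom.
#'
#' @param complex a `toy_complex`
#' @param path output file
#' @export
write_pdb <- function(complex, path) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  emit <- function(name, resname, chain, resid, xyz, element) {
    serial <<- serial + 1L
    writeLines(sprintf(
      "ATOM  %5d %-4s%-4s%s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      serial, substr(name, 1, 4), substr(resname, 1, 4), chain, resid,
      nm_to_A(xyz[1]), nm_to_A(xyz[2]), nm_to_A(xyz[3]), element), con)
  }
  for (i in seq_len(nrow(complex$ligand_coords)))
    emit(if (complex$ligand_heavy[i]) "C" else "H", "LIG", "L", 1L,
         complex$ligand_coords[i, ],
         if (complex$ligand_heavy[i]) "C" else "H")
  gid <- 0L
  for (g in names(complex$groups)) {
    gid <- gid + 1L
    for (i in complex$groups[[g]])
      emit("C", substr(g, 1, 3), "R", gid, complex$receptor_coords[i, ], "C")
  }
  for (i in seq_len(nrow(complex$water_coords)))
    emit("O", "HOH", "W", i, complex$water_coords[i, ], "O")
  writeLines("END", con)
  invisible(path)
}

#' Contact-map specification table
#'
#' Plain-text serialisation of a `contact_map_spec` (pair indices, d0, r0,
#' n, m, s_ref per row plus the formula variant), bit-exact on round trip.
#'
#' @param spec a `contact_map_spec`
#' @param path file path
#' @export
write_contact_map_spec <- function(spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS i j d0 r0 n m s_ref ; variant", spec$variant),
             con)
  for (k in seq_len(nrow(spec$pairs))) {
    p <- spec$switching[[k]]
    writeLines(paste(spec$pairs[k, 1], spec$pairs[k, 2],
                     fmt_num(p$d0), fmt_num(p$r0), p$n, p$m,
                     fmt_num(spec$s_ref[k])), con)
  }
  invisible(path)
}

#' @rdname write_contact_map_spec
#' @export
read_contact_map_spec <- function(path) {
  lines <- readLines(path)
  variant <- sub(".*variant +", "", lines[1])
  toks <- strsplit(trimws(lines[-1]), "[ \t]+")
  m <- matrix(as.numeric(unlist(toks)), ncol = 7, byrow = TRUE)
  contact_map_spec(
    pairs = m[, 1:2],
    switching = lapply(seq_len(nrow(m)), function(k)
      switching_params(m[k, 3], m[k, 4], m[k, 5], m[k, 6])),
    s_ref = m[, 7], variant = variant)
}

#' Write a free-energy surface as a plain-text grid table
#'
#' Axis columns, free energy (kJ/mol) and a visited flag; unvisited bins
#' carry NA free energy.
#'
#' @param fes a `free_energy_surface`
#' @param path output file
#' @export
write_fes <- function(fes, path) {
  g <- expand.grid(fes$axes, KEEP.OUT.ATTRS = FALSE)
  g$free_energy <- as.vector(fes$F)
  g$visited <- as.integer(as.vector(fes$visited))
  write_colvar(g, path)
}

#' Write a frame-index list (0-based, one per line)
#'
#' @param idx 1-based R frame indices
#' @param path output file
#' @export
write_frame_index <- function(idx, path) {
  writeLines(c("# frame indices, 0-based", as.character(idx - 1L)), path)
  invisible(path)
}

#' Run configuration
#'
#' YAML-backed configuration for the pipeline drivers. Unknown top-level
#' keys are rejected; the file's md5 hash is carried into every output
#' manifest so artifacts can be traced to their exact configuration.
#'
#' @param path YAML file
#' @return list of settings with attributes `config_hash` and `config_path`
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("system", "funnel", "colvars", "metad", "smd", "walkers",
             "integrator", "seeds", "output", "units")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  attr(cfg, "config_hash") <- unname(tools::md5sum(path))
  attr(cfg, "config_path") <- path
  cfg
}

#' Write a stage manifest
#'
#' Records the configuration hash, seed and package version next to a
#' stage's artifacts, so any output can be regenerated from its manifest.
#'
#' @param path manifest file to write
#' @param stage stage name
#' @param seed integer seed used
#' @param config_hash configuration hash (or NA)
#' @param extra named list of additional scalar entries
#' @export
write_manifest <- function(path, stage, seed, config_hash = NA, extra = list()) {
  entries <- c(list(stage = stage, seed = seed, config_hash = config_hash,
                    package_version = as.character(utils::packageVersion("funnelmetad")),
                    r_version = paste(R.version$major, R.version$minor, sep = ".")),
               extra)
  yaml::write_yaml(entries, path)
  invisible(path)
}
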