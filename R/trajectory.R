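#' Construct a trajectory object
#'
#' A trajectory bundles an atom table, an `F x A x 3` coordinate array in
#' Angstrom, frame time stamps in picoseconds and an optional role table
#' annotating atoms as hydrogen-bond donors/acceptors, charged atoms or
#' side-chain contact carbons. It is the raw material for contact detection,
#' conformational clustering and RMSF profiling.
#'
#' @param atoms Tibble with columns `atom_id` (0-based, contiguous), `name`
#'   (PDB atom-name convention, e.g. `"CA"`, `"NZ"`), `residue_number`,
#'   `residue_name`, `chain_id`.
#' @param coords Numeric array of dimension `F x A x 3` (frames, atoms, xyz)
#'   in Angstrom; all values finite.
#' @param frame_times Numeric vector of `F` strictly increasing times in ps.
#' @param roles Optional tibble with columns `atom_id`, `role` (one of
#'   `"donor"`, `"hydrogen"`, `"acceptor"`, `"charged"`, `"contact_carbon"`)
#'   and `partner` (for `role == "hydrogen"`, the `atom_id` of the covalently
#'   bound donor; `NA` otherwise).
#' @param run_id Character label for the run.
#'
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(atoms, coords, frame_times = NULL, roles = NULL,
                       run_id = "run") {
  atoms <- tibble::as_tibble(atoms)
  req <- c("atom_id", "name", "residue_number", "residue_name", "chain_id")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (length(dim(coords)) == 2) {
    coords <- array(coords, dim = c(1L, nrow(coords), 3L))
  }
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    stop("coords must be an F x A x 3 array", call. = FALSE)
  }
  n_frames <- dim(coords)[1]
  n_atoms <- dim(coords)[2]
  if (n_atoms != nrow(atoms)) {
    stop("coordinate array has ", n_atoms, " atoms but the atom table has ",
         nrow(atoms), call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (!identical(sort(atoms$atom_id), seq_len(nrow(atoms)) - 1L) &&
      nrow(atoms) > 0) {
    stop("atom_id values must be unique and contiguous from 0", call. = FALSE)
  }
  if (is.null(frame_times)) frame_times <- seq_len(n_frames) - 1
  if (length(frame_times) != n_frames || any(diff(frame_times) <= 0)) {
    stop("frame_times must have one strictly increasing value per frame",
         call. = FALSE)
  }
  roles <- validate_roles(roles, atoms)
  structure(
    list(atoms = atoms, coords = coords,
         frame_times = as.numeric(frame_times),
         roles = roles, run_id = run_id),
    class = "trajectory"
  )
}

validate_roles <- function(roles, atoms) {
  if (is.null(roles)) {
    return(tibble::tibble(atom_id = integer(), role = character(),
                          partner = integer()))
  }
  roles <- tibble::as_tibble(roles)
  if (!all(c("atom_id", "role") %in% names(roles))) {
    stop("role table needs columns atom_id and role", call. = FALSE)
  }
  if (!"partner" %in% names(roles)) roles$partner <- NA_integer_
  allowed <- c("donor", "hydrogen", "acceptor", "charged", "contact_carbon")
  bad <- setdiff(unique(roles$role), allowed)
  if (length(bad) > 0) {
    stop("unknown role tag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(roles$atom_id %in% atoms$atom_id)) {
    stop("role table references atom_id values absent from the atom table",
         call. = FALSE)
  }
  hyd <- roles[roles$role == "hydrogen", ]
  if (nrow(hyd) > 0) {
    donors <- roles$atom_id[roles$role == "donor"]
    if (any(is.na(hyd$partner)) || !all(hyd$partner %in% donors)) {
      stop("every hydrogen role must name a partner atom_id tagged as donor",
           call. = FALSE)
    }
  }
  roles
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory '%s'> %d frames x %d atoms, t = [%g, %g] ps, %d role tags\n",
    x$run_id, n_frames(x), nrow(x$atoms),
    min(x$frame_times), max(x$frame_times), nrow(x$roles)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A trajectory.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame as an A x 3 matrix
#' @param traj A trajectory.
#' @param i Frame index (1-based).
#' @return Numeric `A x 3` matrix.
#' @export
frame_coords <- function(traj, i) {
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  m
}

#' Subset a trajectory by frame indices
#' @param traj A trajectory.
#' @param idx Integer vector of frame indices to keep (1-based, increasing).
#' @return A trajectory with the selected frames.
#' @export
subset_frames <- function(traj, idx) {
  trajectory(traj$atoms, traj$coords[idx, , , drop = FALSE],
             traj$frame_times[idx], traj$roles, traj$run_id)
}

#' Select atom indices by chain, residue and atom name
#'
#' @param traj A trajectory.
#' @param chain Optional chain id(s).
#' @param residues Optional residue numbers.
#' @param atom_names Optional atom names (e.g. `c("N", "CA", "C")`).
#' @return Integer vector of 1-based atom indices (rows of the atom table).
#' @export
select_atoms <- function(traj, chain = NULL, residues = NULL,
                         atom_names = NULL) {
  keep <- rep(TRUE, nrow(traj$atoms))
  if (!is.null(chain)) keep <- keep & traj$atoms$chain_id %in% chain
  if (!is.null(residues)) keep <- keep & traj$atoms$residue_number %in% residues
  if (!is.null(atom_names)) keep <- keep & traj$atoms$name %in% atom_names
  which(keep)
}

#' Select backbone atoms (N, CA, C)
#'
#' Convenience wrapper used by leader clustering and RMSF, which both operate
#' on the peptide backbone.
#'
#' @inheritParams select_atoms
#' @return Integer vector of 1-based atom indices.
#' @export
select_backbone <- function(traj, chain = NULL, residues = NULL) {
  select_atoms(traj, chain = chain, residues = residues,
               atom_names = c("N", "CA", "C"))
}

#' Discard the equilibration segment of a trajectory
#'
#' Removes every frame recorded before `burn_in_ns` nanoseconds, the standard
#' guard against bias from the starting configuration. Frames with
#' `time >= burn_in_ns` are kept.
#'
#' @param traj A trajectory.
#' @param burn_in_ns Burn-in length in ns (default 50).
#' @return The truncated trajectory.
#' @export
discard_equilibration <- function(traj, burn_in_ns = 50) {
  burn_ps <- burn_in_ns * 1000
  keep <- which(traj$frame_times >= burn_ps)
  if (length(keep) == 0) {
    stop("burn-in of ", burn_in_ns,
         " ns is at least as long as the whole trajectory", call. = FALSE)
  }
  if (length(keep) == n_frames(traj)) return(traj)
  subset_frames(traj, keep)
}

# ---- I/O ---------------------------------------------------------------

#' Read a trajectory from disk
#'
#' Supports two plain-text dialects: multi-model PDB (`MODEL`/`ENDMDL`
#' delimited; only `ATOM`/`HETATM` records are read, occupancy and B-factor
#' ignored) and frame-stacked XYZ. All frames must carry the same atoms in
#' the same order; a mismatch is a hard error naming the offending frame.
#'
#' @param path Path to the coordinate file.
#' @param format `"pdb_multimodel"` or `"xyz"`.
#' @param topology_path Optional role-table TSV (see [read_topology()]);
#'   when given, role tags are resolved against the parsed atoms.
#' @param dt_ps Frame spacing in ps used to synthesise time stamps
#'   (`0, dt, 2 dt, ...`); default 1 ps.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, format = c("pdb_multimodel", "xyz"),
                            topology_path = NULL, dt_ps = 1) {
  format <- match.arg(format)
  parsed <- switch(format,
    pdb_multimodel = parse_pdb_multimodel(path),
    xyz = parse_xyz(path))
  roles <- NULL
  if (!is.null(topology_path)) {
    roles <- read_topology(topology_path, parsed$atoms)
  }
  trajectory(parsed$atoms, parsed$coords,
             frame_times = (seq_len(dim(parsed$coords)[1]) - 1) * dt_ps,
             roles = roles,
             run_id = tools::file_path_sans_ext(basename(path)))
}

parse_pdb_multimodel <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- grepl("^MODEL", lines)
  # Single-model files may omit MODEL records entirely.
  model_id <- cumsum(model_starts)
  if (!any(model_starts)) model_id <- rep(1L, length(lines))
  model_id[model_id == 0] <- 1L
  atom_lines <- lines[is_atom]
  atom_models <- model_id[is_atom]
  if (length(atom_lines) == 0) stop("no ATOM/HETATM records in ", path,
                                    call. = FALSE)
  models <- split(atom_lines, atom_models)
  counts <- lengths(models)
  if (length(unique(counts)) != 1) {
    ref_n <- counts[[1]]
    bad <- names(counts)[counts != ref_n][1]
    stop("model ", bad, " of ", path, " has ", counts[[bad]],
         " atoms; expected ", ref_n, call. = FALSE)
  }
  first <- models[[1]]
  atoms <- tibble::tibble(
    atom_id = seq_along(first) - 1L,
    name = trimws(substr(first, 13, 16)),
    residue_name = trimws(substr(first, 18, 20)),
    chain_id = substr(first, 22, 22),
    residue_number = as.integer(trimws(substr(first, 23, 26)))
  )[, c("atom_id", "name", "residue_number", "residue_name", "chain_id")]
  coords <- array(NA_real_, dim = c(length(models), length(first), 3))
  for (f in seq_along(models)) {
    ml <- models[[f]]
    coords[f, , 1] <- as.numeric(substr(ml, 31, 38))
    coords[f, , 2] <- as.numeric(substr(ml, 39, 46))
    coords[f, , 3] <- as.numeric(substr(ml, 47, 54))
  }
  if (!all(is.finite(coords))) {
    stop("non-numeric coordinates in ", path, call. = FALSE)
  }
  list(atoms = atoms, coords = coords)
}

parse_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) %% 1 == 0]
  frames <- list()
  names_list <- list()
  i <- 1
  f <- 0
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("expected an atom count at line ", i, " of ", path,
                       call. = FALSE)
    f <- f + 1
    if (i + 1 + n > length(lines)) {
      stop("frame ", f, " of ", path, " is truncated", call. = FALSE)
    }
    body <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(body), "\\s+")
    if (any(lengths(parts) < 4)) {
      stop("malformed coordinate line in frame ", f, " of ", path,
           call. = FALSE)
    }
    names_list[[f]] <- vapply(parts, `[`, "", 1)
    frames[[f]] <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                          ncol = 3, byrow = TRUE)
    i <- i + 2 + n
  }
  counts <- vapply(frames, nrow, 0L)
  if (length(unique(counts)) != 1) {
    bad <- which(counts != counts[1])[1]
    stop("frame ", bad, " of ", path, " has ", counts[bad],
         " atoms; expected ", counts[1], call. = FALSE)
  }
  atoms <- tibble::tibble(
    atom_id = seq_len(counts[1]) - 1L,
    name = names_list[[1]],
    residue_number = 1L,
    residue_name = "UNK",
    chain_id = "A"
  )
  coords <- array(NA_real_, dim = c(length(frames), counts[1], 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  list(atoms = atoms, coords = coords)
}

#' Write a trajectory to disk
#'
#' Emits the same minimal dialects [read_trajectory()] reads. The first line
#' of every file is a comment header carrying the tool version (a `REMARK`
#' record for PDB, the per-frame comment line for XYZ).
#'
#' @param traj A trajectory.
#' @param path Output path.
#' @param format `"pdb_multimodel"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("pdb_multimodel", "xyz")) {
  format <- match.arg(format)
  version <- as.character(utils::packageVersion("pdzmodes"))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb_multimodel") {
    writeLines(sprintf("REMARK   1 written by pdzmodes %s", version), con)
    for (f in seq_len(n_frames(traj))) {
      writeLines(sprintf("MODEL     %4d", f), con)
      xyz <- frame_coords(traj, f)
      a <- traj$atoms
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        a$atom_id + 1L,
        ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
        a$residue_name, a$chain_id, a$residue_number,
        xyz[, 1], xyz[, 2], xyz[, 3]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    for (f in seq_len(n_frames(traj))) {
      writeLines(as.character(nrow(traj$atoms)), con)
      writeLines(sprintf("pdzmodes %s frame %d t=%g ps", version, f,
                         traj$frame_times[f]), con)
      xyz <- frame_coords(traj, f)
      writeLines(sprintf("%s %.6f %.6f %.6f", traj$atoms$name,
                         xyz[, 1], xyz[, 2], xyz[, 3]), con)
    }
  }
  invisible(path)
}

#' Read an atom-role topology table
#'
#' The table is a TSV with columns `chain`, `residue_number`, `atom_name`,
#' `role_tag` and optional `partner_atom_name` (required for
#' `role_tag == "hydrogen"`, naming the covalently bound donor atom within
#' the same residue). Roles drive contact-spec resolution: `donor`/`hydrogen`/
#' `acceptor` for hydrogen bonds, `charged`/`contact_carbon` for salt bridges.
#'
#' @param path TSV path.
#' @param atoms Atom table the selectors must resolve against.
#' @return Role tibble (`atom_id`, `role`, `partner`).
#' @export
read_topology <- function(path, atoms) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#")
  req <- c("chain", "residue_number", "atom_name", "role_tag")
  if (!all(req %in% names(tab))) {
    stop("topology TSV needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!"partner_atom_name" %in% names(tab)) tab$partner_atom_name <- NA
  lookup <- function(chain, resnum, name) {
    hit <- which(atoms$chain_id == chain & atoms$residue_number == resnum &
                   atoms$name == name)
    if (length(hit) != 1) {
      stop("topology row ", chain, ":", resnum, ":", name,
           " matches ", length(hit), " atoms", call. = FALSE)
    }
    atoms$atom_id[hit]
  }
  roles <- purrr::pmap_dfr(tab, function(chain, residue_number, atom_name,
                                         role_tag, partner_atom_name, ...) {
    id <- lookup(chain, residue_number, atom_name)
    partner <- NA_integer_
    if (!is.na(partner_atom_name) && nzchar(partner_atom_name)) {
      partner <- lookup(chain, residue_number, partner_atom_name)
    }
    tibble::tibble(atom_id = id, role = role_tag, partner = partner)
  })
  validate_roles(roles, atoms)
}

#' Write an atom-role topology table
#' @param traj Trajectory whose `roles` table is written.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(traj, path) {
  a <- traj$atoms
  r <- traj$roles
  idx <- match(r$atom_id, a$atom_id)
  pidx <- match(r$partner, a$atom_id)
  out <- data.frame(
    chain = a$chain_id[idx],
    residue_number = a$residue_number[idx],
    atom_name = a$name[idx],
    role_tag = r$role,
    partner_atom_name = ifelse(is.na(pidx), "", a$name[pidx])
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# written by pdzmodes %s",
                     utils::packageVersion("pdzmodes")), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Standard role tags for the 20 amino acids
#'
#' Convenience preset mapping residue names to the role tags contact
#' detection needs: charged side-chain atoms and the last two carbons before
#' them for the ionisable residues (LYS, ARG, ASP, GLU, HIS), plus backbone
#' donor/acceptor assignments. Returns role rows for every atom of `atoms`
#' the preset covers.
#'
#' @param atoms Atom table.
#' @return Role tibble suitable for [trajectory()].
#' @export
standard_roles <- function(atoms) {
  side <- list(
    LYS = list(charged = "NZ", carbons = c("CD", "CE")),
    ARG = list(charged = c("NH1", "NH2", "CZ"), carbons = c("CD", "CZ")),
    ASP = list(charged = c("OD1", "OD2"), carbons = c("CB", "CG")),
    GLU = list(charged = c("OE1", "OE2"), carbons = c("CG", "CD")),
    HIS = list(charged = c("ND1", "NE2"), carbons = c("CG", "CD2"))
  )
  rows <- list()
  for (i in seq_len(nrow(atoms))) {
    res <- atoms$residue_name[i]
    nm <- atoms$name[i]
    if (!is.null(side[[res]])) {
      if (nm %in% side[[res]]$charged) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          atom_id = atoms$atom_id[i], role = "charged",
          partner = NA_integer_)
      }
      if (nm %in% side[[res]]$carbons) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          atom_id = atoms$atom_id[i], role = "contact_carbon",
          partner = NA_integer_)
      }
    }
    if (nm == "O") {
      rows[[length(rows) + 1]] <- tibble::tibble(
        atom_id = atoms$atom_id[i], role = "acceptor", partner = NA_integer_)
    }
    if (nm == "N") {
      rows[[length(rows) + 1]] <- tibble::tibble(
        atom_id = atoms$atom_id[i], role = "donor", partner = NA_integer_)
    }
    if (nm %in% c("H", "HN")) {
      donor <- which(atoms$chain_id == atoms$chain_id[i] &
                       atoms$residue_number == atoms$residue_number[i] &
                       atoms$name == "N")
      if (length(donor) == 1) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          atom_id = atoms$atom_id[i], role = "hydrogen",
          partner = atoms$atom_id[donor])
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(atom_id = integer(), role = character(),
                          partner = integer()))
  }
  dplyr::bind_rows(rows)
}
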