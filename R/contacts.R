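#' Hydrogen-bond geometric test for one frame
#'
#' A hydrogen bond is formed when the donor-acceptor distance is at most
#' `dist_cutoff` and the angle at the donor between the donor-hydrogen and
#' donor-acceptor vectors is at most `angle_cutoff_deg`.
#'
#' @param frame `A x 3` coordinate matrix.
#' @param donor,hydrogen,acceptor 0-based atom ids (distinct).
#' @param angle_cutoff_deg Angle cutoff at the donor in degrees (default 30).
#' @param dist_cutoff Donor-acceptor distance cutoff in Angstrom
#'   (default 3.6).
#' @return Logical scalar.
#' @export
detect_hbond <- function(frame, donor, hydrogen, acceptor,
                         angle_cutoff_deg = 30, dist_cutoff = 3.6) {
  ids <- c(donor, hydrogen, acceptor)
  if (anyDuplicated(ids) > 0) stop("donor, hydrogen and acceptor must be distinct",
                                   call. = FALSE)
  if (any(ids < 0) || any(ids >= nrow(frame))) {
    stop("atom id out of range", call. = FALSE)
  }
  d <- frame[donor + 1L, ]
  h <- frame[hydrogen + 1L, ]
  a <- frame[acceptor + 1L, ]
  da <- a - d
  dh <- h - d
  dist_da <- sqrt(sum(da^2))
  if (dist_da > dist_cutoff) return(FALSE)
  nh <- sqrt(sum(dh^2))
  if (nh < 1e-9 || dist_da < 1e-9) {
    stop("coincident donor/hydrogen/acceptor coordinates: angle undefined",
         call. = FALSE)
  }
  cosang <- sum(dh * da) / (nh * dist_da)
  cosang <- min(1, max(-1, cosang))
  angle <- acos(cosang) * 180 / pi
  angle <= angle_cutoff_deg
}

#' Ionic-contact (salt-bridge) geometric test for one frame
#'
#' A salt bridge is formed when the two last side-chain carbons before the
#' charged atoms of the two residues come closer than `cutoff` (strict
#' inequality): the minimum pairwise distance over the two carbon sets is
#' compared against the cutoff.
#'
#' @param frame `A x 3` coordinate matrix.
#' @param carbons_a,carbons_b Non-empty sets of 0-based atom ids.
#' @param cutoff Distance cutoff in Angstrom (default 5).
#' @return Logical scalar.
#' @export
detect_ionic <- function(frame, carbons_a, carbons_b, cutoff = 5.0) {
  if (length(carbons_a) == 0 || length(carbons_b) == 0) {
    stop("both carbon sets must be non-empty", call. = FALSE)
  }
  pa <- frame[carbons_a + 1L, , drop = FALSE]
  pb <- frame[carbons_b + 1L, , drop = FALSE]
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
  min(sqrt(pmax(d2, 0))) < cutoff
}

#' Define a candidate interaction to monitor
#'
#' A contact spec names one interaction (e.g. `"-7:331"`) and gives the two
#' sides as atom selectors of the form `chain:resnum:atomname`, where each
#' field may be `*`. For `kind = "hbond"` one side must resolve to at least
#' one donor/hydrogen pair and the other to at least one acceptor (role tags
#' come from the trajectory's topology); for `kind = "ionic"` both sides must
#' resolve to at least one `contact_carbon`. When several geometries resolve,
#' the contact is formed in a frame if ANY of them passes the test.
#'
#' @param name Label, e.g. `"-7:331"`.
#' @param kind `"hbond"` or `"ionic"`.
#' @param side_a,side_b Selector strings.
#' @param angle_cutoff_deg,dist_cutoff,ionic_cutoff Geometric cutoffs
#'   (degrees / Angstrom) passed to the detectors.
#' @return An object of class `"contact_spec"`.
#' @export
contact_spec <- function(name, kind = c("hbond", "ionic"), side_a, side_b,
                         angle_cutoff_deg = 30, dist_cutoff = 3.6,
                         ionic_cutoff = 5.0) {
  kind <- match.arg(kind)
  structure(
    list(name = name, kind = kind, side_a = side_a, side_b = side_b,
         angle_cutoff_deg = angle_cutoff_deg, dist_cutoff = dist_cutoff,
         ionic_cutoff = ionic_cutoff),
    class = "contact_spec"
  )
}

match_selector <- function(atoms, selector) {
  parts <- strsplit(selector, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3) {
    stop("selector '", selector, "' must be chain:resnum:atomname",
         call. = FALSE)
  }
  keep <- rep(TRUE, nrow(atoms))
  if (parts[1] != "*") keep <- keep & atoms$chain_id == parts[1]
  if (parts[2] != "*") keep <- keep & atoms$residue_number == as.integer(parts[2])
  if (parts[3] != "*") keep <- keep & atoms$name == parts[3]
  atoms$atom_id[keep]
}

resolve_spec <- function(spec, traj) {
  ids_a <- match_selector(traj$atoms, spec$side_a)
  ids_b <- match_selector(traj$atoms, spec$side_b)
  roles <- traj$roles
  role_ids <- function(ids, role) intersect(ids, roles$atom_id[roles$role == role])
  if (spec$kind == "ionic") {
    ca <- role_ids(ids_a, "contact_carbon")
    cb <- role_ids(ids_b, "contact_carbon")
    if (length(ca) == 0 || length(cb) == 0) {
      stop("contact '", spec$name,
           "': both sides must resolve to >= 1 contact_carbon", call. = FALSE)
    }
    return(list(kind = "ionic", carbons_a = ca, carbons_b = cb))
  }
  dh_pairs <- function(ids) {
    donors <- role_ids(ids, "donor")
    hyd <- roles[roles$role == "hydrogen" & roles$partner %in% donors, ]
    if (nrow(hyd) == 0) return(NULL)
    data.frame(donor = hyd$partner, hydrogen = hyd$atom_id)
  }
  pa <- dh_pairs(ids_a); acc_b <- role_ids(ids_b, "acceptor")
  pb <- dh_pairs(ids_b); acc_a <- role_ids(ids_a, "acceptor")
  if (!is.null(pa) && length(acc_b) > 0) {
    list(kind = "hbond", pairs = pa, acceptors = acc_b)
  } else if (!is.null(pb) && length(acc_a) > 0) {
    list(kind = "hbond", pairs = pb, acceptors = acc_a)
  } else {
    stop("contact '", spec$name, "': need a donor/hydrogen pair on one side ",
         "and an acceptor on the other", call. = FALSE)
  }
}

#' Per-frame contact formation records
#'
#' Evaluates every spec in every frame. For specs resolving to several
#' geometries (multiple donor hydrogens, carboxylate oxygens, carbon pairs)
#' the contact is formed if any resolved geometry passes.
#'
#' @param traj A [trajectory()] with role annotations.
#' @param specs List of [contact_spec()] objects.
#' @return A tibble of class `"contact_records"` with one row per spec:
#'   columns `name`, `kind`, `occupancy` and the list-column `formed`
#'   (length-F logical vector per row).
#' @export
contact_timeseries <- function(traj, specs) {
  if (inherits(specs, "contact_spec")) specs <- list(specs)
  nf <- n_frames(traj)
  # distance between two atoms across all frames at once
  pair_dist <- function(i, j) {
    d <- traj$coords[, i + 1L, , drop = FALSE] -
      traj$coords[, j + 1L, , drop = FALSE]
    dim(d) <- c(nf, 3L)
    sqrt(rowSums(d^2))
  }
  rows <- purrr::map(specs, function(spec) {
    res <- resolve_spec(spec, traj)
    if (res$kind == "ionic") {
      formed <- rep(FALSE, nf)
      for (i in res$carbons_a) {
        for (j in res$carbons_b) {
          formed <- formed | (pair_dist(i, j) < spec$ionic_cutoff)
        }
      }
    } else {
      formed <- rep(FALSE, nf)
      cos_cut <- cos(spec$angle_cutoff_deg * pi / 180)
      for (p in seq_len(nrow(res$pairs))) {
        don <- res$pairs$donor[p]
        hyd <- res$pairs$hydrogen[p]
        dh <- traj$coords[, hyd + 1L, , drop = FALSE] -
          traj$coords[, don + 1L, , drop = FALSE]
        dim(dh) <- c(nf, 3L)
        nh <- sqrt(rowSums(dh^2))
        for (acc in res$acceptors) {
          da <- traj$coords[, acc + 1L, , drop = FALSE] -
            traj$coords[, don + 1L, , drop = FALSE]
          dim(da) <- c(nf, 3L)
          nd <- sqrt(rowSums(da^2))
          if (any(nh < 1e-9) || any(nd < 1e-9)) {
            stop("coincident donor/hydrogen/acceptor coordinates in contact '",
                 spec$name, "'", call. = FALSE)
          }
          cosang <- rowSums(dh * da) / (nh * nd)
          formed <- formed |
            (nd <= spec$dist_cutoff & cosang >= cos_cut - 1e-12)
        }
      }
    }
    tibble::tibble(name = spec$name, kind = spec$kind,
                   occupancy = mean(formed), formed = list(formed))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "frame_times") <- traj$frame_times
  class(out) <- c("contact_records", class(out))
  out
}

#' Cumulative occupancy of a set of contacts
#'
#' Fraction of frames in which at least one of the named contacts is formed
#' (logical OR across records). This is the quantity behind statements like
#' "the loop and the ligand are in contact via salt bridges for 44% of the
#' time".
#'
#' @param records A [contact_timeseries()] result.
#' @param subset Character vector of contact names (default: all).
#' @return Fraction in `[0, 1]`.
#' @export
cumulative_occupancy <- function(records, subset = records$name) {
  if (length(subset) == 0) stop("subset must be non-empty", call. = FALSE)
  unknown <- setdiff(subset, records$name)
  if (length(unknown) > 0) {
    stop("unknown contact name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  series <- records$formed[match(subset, records$name)]
  mean(Reduce(`|`, series))
}

#' Write per-contact and summary TSVs
#' @param records A [contact_timeseries()] result.
#' @param dir Output directory (created if needed).
#' @return Paths of written files, invisibly.
#' @export
write_contacts <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  times <- attr(records, "frame_times")
  paths <- character(0)
  for (i in seq_len(nrow(records))) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", records$name[i])
    p <- file.path(dir, paste0("contact_", safe, ".tsv"))
    readr::write_tsv(tibble::tibble(frame_time = times,
                                    formed = as.integer(records$formed[[i]])),
                     p)
    paths <- c(paths, p)
  }
  summary_path <- file.path(dir, "contacts_summary.tsv")
  readr::write_tsv(dplyr::select(tibble::as_tibble(records), "name", "kind",
                                 "occupancy"), summary_path)
  invisible(c(paths, summary_path))
}
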