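abort_io <- function(msg, class = "hcmgr_unsupported_cell") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

layer_codes <- function(layer) {
  lv <- c(single = 0L, media = 1L, adventitia = 2L)
  unname(lv[layer])
}

layer_names <- function(code) {
  c("single", "media", "adventitia")[code + 1L]
}

#' Read a hexahedral mesh from file
#'
#' Supports gmsh `.msh` (ASCII versions 2.2 and 4.1) and legacy ASCII VTK
#' unstructured grids containing hexahedral cells only (VTK cell type 12 /
#' gmsh element type 5, identical node ordering).  gmsh physical volume
#' names `media`/`adventitia` become layer labels; with two unnamed tags the
#' lower tag is the media.  Without layer tags a warning is raised and all
#' elements are labelled `single`.
#'
#' @param path file path.
#' @return a `hex_mesh` (no node/facet sets, no frames; attach frames with
#'   [compute_local_frames()]).
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) abort_io(paste("file not found:", path),
                                   class = "hcmgr_file_not_found")
  head1 <- readLines(path, n = 1L)
  if (grepl("vtk DataFile", head1, ignore.case = TRUE) ||
      grepl("^#", head1)) read_mesh_vtk(path) else read_mesh_gmsh(path)
}

read_mesh_vtk <- function(path) {
  tok <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  pos <- which(toupper(tok) == "POINTS")[1]
  n <- as.integer(tok[pos + 1])
  nodes <- matrix(as.numeric(tok[(pos + 3):(pos + 2 + 3 * n)]), n, 3, byrow = TRUE)
  pos <- which(toupper(tok) == "CELLS")[1]
  ne <- as.integer(tok[pos + 1])
  ntot <- as.integer(tok[pos + 2])
  cdat <- as.integer(tok[(pos + 3):(pos + 2 + ntot)])
  pos <- which(toupper(tok) == "CELL_TYPES")[1]
  ctypes <- as.integer(tok[(pos + 2):(pos + 1 + ne)])
  if (any(ctypes != 12L)) abort_io("unsupported cell type: only hexahedra (VTK type 12) are handled")
  elems <- matrix(0L, ne, 8)
  k <- 1L
  for (e in seq_len(ne)) {
    cnt <- cdat[k]
    if (cnt != 8L) abort_io("unsupported cell: expected 8 nodes per hexahedron")
    elems[e, ] <- cdat[(k + 1):(k + 8)] + 1L
    k <- k + 9L
  }
  layer <- rep("single", ne)
  pos <- which(toupper(tok) == "CELL_DATA")
  lpos <- which(tok == "layer")
  if (length(lpos)) {
    lpos <- lpos[1]
    # SCALARS layer int 1 / LOOKUP_TABLE default / values
    vals <- as.integer(tok[(lpos + 5):(lpos + 4 + ne)])
    layer <- layer_names(vals)
  } else {
    warning("no layer tags in VTK file; assigning single layer")
  }
  new_hex_mesh(nodes, elems, layer, list(), list(),
               meta = list(type = "external", source = path))
}

read_mesh_gmsh <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    a <- which(lines == paste0("$", name))
    b <- which(lines == paste0("$End", name))
    if (!length(a) || !length(b)) return(NULL)
    lines[(a[1] + 1):(b[1] - 1)]
  }
  fmt <- strsplit(trimws(sec("MeshFormat")[1]), "\\s+")[[1]]
  ver <- as.numeric(fmt[1])
  phys_names <- list()
  pn <- sec("PhysicalNames")
  if (!is.null(pn)) {
    for (ln in pn[-1]) {
      p <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(p) >= 3)
        phys_names[[p[2]]] <- gsub('"', "", paste(p[-(1:2)], collapse = " "))
    }
  }
  if (ver < 4) {
    nd <- sec("Nodes")
    n <- as.integer(nd[1])
    ndm <- do.call(rbind, lapply(nd[2:(n + 1)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    ids <- as.integer(ndm[, 1])
    nodes <- ndm[, 2:4, drop = FALSE]
    idmap <- integer(max(ids)); idmap[ids] <- seq_len(n)
    el <- sec("Elements")
    nel <- as.integer(el[1])
    conn <- list(); tags <- integer(0)
    for (ln in el[2:(nel + 1)]) {
      p <- as.integer(strsplit(trimws(ln), "\\s+")[[1]])
      etype <- p[2]
      if (etype != 5L) next  # skip lower-dimensional elements
      ntag <- p[3]
      phys <- if (ntag >= 1) p[4] else NA_integer_
      nn <- p[(4 + ntag):(11 + ntag)]
      conn[[length(conn) + 1L]] <- idmap[nn]
      tags <- c(tags, phys)
    }
    if (!length(conn)) abort_io("no hexahedral elements in gmsh file")
    elems <- do.call(rbind, conn)
  } else {
    # v4.1: entity blocks; map volume entity tag -> physical tag via $Entities
    ent_phys <- list()
    en <- sec("Entities")
    if (!is.null(en)) {
      cnt <- as.integer(strsplit(trimws(en[1]), "\\s+")[[1]])
      row <- 1L
      skip <- function(nrow) row <<- row + nrow
      skip(cnt[1]); skip(cnt[2]); skip(cnt[3])
      if (length(cnt) >= 4 && cnt[4] > 0) {
        for (v in seq_len(cnt[4])) {
          row <- row + 1L
          p <- as.numeric(strsplit(trimws(en[row]), "\\s+")[[1]])
          np <- as.integer(p[8])
          if (!is.na(np) && np >= 1) ent_phys[[as.character(as.integer(p[1]))]] <-
              as.integer(p[9])
        }
      }
    }
    nd <- sec("Nodes")
    hdr <- as.integer(strsplit(trimws(nd[1]), "\\s+")[[1]])
    nblk <- hdr[1]; n <- hdr[2]
    ids <- integer(0); xyz <- list()
    row <- 1L
    for (b in seq_len(nblk)) {
      row <- row + 1L
      bh <- as.integer(strsplit(trimws(nd[row]), "\\s+")[[1]])
      nb <- bh[4]
      if (nb == 0) next
      bids <- as.integer(nd[(row + 1):(row + nb)])
      coords <- do.call(rbind, lapply(nd[(row + nb + 1):(row + 2 * nb)],
        function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])[1:3]))
      ids <- c(ids, bids); xyz[[b]] <- coords
      row <- row + 2L * nb
    }
    nodes <- do.call(rbind, xyz)
    idmap <- integer(max(ids)); idmap[ids] <- seq_along(ids)
    el <- sec("Elements")
    row <- 1L
    ehdr <- as.integer(strsplit(trimws(el[1]), "\\s+")[[1]])
    conn <- list(); tags <- integer(0)
    for (b in seq_len(ehdr[1])) {
      row <- row + 1L
      bh <- as.integer(strsplit(trimws(el[row]), "\\s+")[[1]])
      edim <- bh[1]; etag <- bh[2]; etype <- bh[3]; nb <- bh[4]
      for (r in seq_len(nb)) {
        row <- row + 1L
        if (etype != 5L) next
        p <- as.integer(strsplit(trimws(el[row]), "\\s+")[[1]])
        conn[[length(conn) + 1L]] <- idmap[p[2:9]]
        pt <- ent_phys[[as.character(etag)]]
        tags <- c(tags, if (is.null(pt)) NA_integer_ else pt)
      }
    }
    if (!length(conn)) abort_io("no hexahedral elements in gmsh file")
    elems <- do.call(rbind, conn)
  }
  layer <- rep("single", nrow(elems))
  if (all(is.na(tags))) {
    warning("no physical volume tags; assigning single layer")
  } else {
    ut <- sort(unique(tags[!is.na(tags)]))
    for (t in ut) {
      nm <- phys_names[[as.character(t)]]
      if (is.null(nm)) nm <- if (length(ut) >= 2 && t == ut[2]) "adventitia"
                        else if (length(ut) >= 2) "media" else "single"
      layer[!is.na(tags) & tags == t] <- nm
    }
  }
  storage.mode(elems) <- "integer"
  new_hex_mesh(nodes, elems, layer, list(), list(),
               meta = list(type = "external", source = path))
}

#' Write a mesh to gmsh v2.2 or legacy VTK format
#'
#' @param path output path; format from extension (`.msh` gmsh v2.2 ASCII,
#'   anything else legacy ASCII VTK).
#' @param mesh a `hex_mesh`.
#' @export
write_mesh <- function(path, mesh) {
  if (grepl("\\.msh$", path)) write_mesh_gmsh(path, mesh)
  else write_fields(path, mesh)
  invisible(path)
}

write_mesh_gmsh <- function(path, mesh) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat"), con)
  lyr <- unique(mesh$layer)
  tag_of <- stats::setNames(seq_along(lyr), lyr)
  writeLines("$PhysicalNames", con)
  writeLines(as.character(length(lyr)), con)
  for (l in lyr) writeLines(sprintf('3 %d "%s"', tag_of[[l]], l), con)
  writeLines("$EndPhysicalNames", con)
  n <- nrow(mesh$nodes)
  writeLines(c("$Nodes", as.character(n)), con)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(n), mesh$nodes[, 1],
                     mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(c("$EndNodes", "$Elements", as.character(nrow(mesh$elems))), con)
  for (e in seq_len(nrow(mesh$elems))) {
    t <- tag_of[[mesh$layer[e]]]
    writeLines(paste(c(e, 5L, 2L, t, t, mesh$elems[e, ]), collapse = " "), con)
  }
  writeLines("$EndElements", con)
}

#' Export a mesh and fields as a legacy ASCII VTK unstructured grid
#'
#' @param path output path.
#' @param mesh a `hex_mesh`.
#' @param point_data named list of per-node vectors (scalars) or n x 3
#'   matrices (vectors, e.g. displacement).
#' @param cell_data named list of per-element vectors.
#' @export
write_fields <- function(path, mesh, point_data = list(), cell_data = list()) {
  con <- file(path, "w"); on.exit(close(con))
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0", "hcmgr fields", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", ne, 9L * ne), con)
  writeLines(apply(mesh$elems - 1L, 1, function(r)
    paste(c(8L, r), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("12", ne), con)
  writeLines(sprintf("CELL_DATA %d", ne), con)
  writeLines(c("SCALARS layer int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(layer_codes(mesh$layer)), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.10g", cell_data[[nm]]), con)
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) == 3) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.10g", v), con)
      }
    }
  }
  invisible(path)
}
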