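#' Export a case geometry as a triangulated STL surface
#'
#' Lofts a watertight tube surface through the ordered cross-section
#' boundaries (all boundaries share the same vertex count) and caps both
#' ends with triangle fans.
#'
#' @param case a `case_geometry`.
#' @param path output file path.
#' @param format `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
export_surface <- function(case, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  rings <- lapply(case$sections, `[[`, "boundary3d")
  nv <- nrow(rings[[1]])
  nring <- length(rings)
  tri <- vector("list", 2 * nv * (nring - 1) + 2 * (nv - 2))
  k <- 0L
  for (i in seq_len(nring - 1)) {
    A <- rings[[i]]; B <- rings[[i + 1]]
    for (j in seq_len(nv)) {
      j2 <- if (j == nv) 1L else j + 1L
      k <- k + 1L; tri[[k]] <- rbind(A[j, ], B[j, ], B[j2, ])
      k <- k + 1L; tri[[k]] <- rbind(A[j, ], B[j2, ], A[j2, ])
    }
  }
  # end caps: fans anchored at the first boundary vertex
  capA <- rings[[1]]; capB <- rings[[nring]]
  for (j in 2:(nv - 1)) {
    k <- k + 1L; tri[[k]] <- rbind(capA[1, ], capA[j + 1, ], capA[j, ])
    k <- k + 1L; tri[[k]] <- rbind(capB[1, ], capB[j, ], capB[j + 1, ])
  }
  tri <- tri[seq_len(k)]
  normals <- t(vapply(tri, function(tr) {
    n <- cross3(tr[2, ] - tr[1, ], tr[3, ] - tr[1, ])
    l <- sqrt(sum(n^2))
    if (l < 1e-15) c(0, 0, 1) else n / l
  }, numeric(3)))

  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(length(tri)), con, size = 4, endian = "little")
    for (i in seq_along(tri)) {
      writeBin(as.numeric(c(normals[i, ], t(tri[[i]]))), con, size = 4,
               endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid centerflow", con)
    for (i in seq_along(tri)) {
      writeLines(sprintf("  facet normal %e %e %e", normals[i, 1], normals[i, 2], normals[i, 3]), con)
      writeLines("    outer loop", con)
      for (r in 1:3) {
        writeLines(sprintf("      vertex %e %e %e", tri[[i]][r, 1], tri[[i]][r, 2], tri[[i]][r, 3]), con)
      }
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid centerflow", con)
  }
  invisible(path)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Read a (binary or ASCII) STL surface
#'
#' @param path STL file path.
#' @return list with `vertices` (3n x 3 matrix, one triangle per three rows)
#'   and `n_triangles`.
#' @export
read_stl <- function(path) {
  head_raw <- readBin(path, "raw", n = 5)
  is_ascii <- identical(rawToChar(head_raw), "solid")
  if (is_ascii) {
    lines <- readLines(path)
    vx <- grep("^\\s*vertex", lines, value = TRUE)
    vals <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"), function(p) as.numeric(p[2:4])))
    return(list(vertices = vals, n_triangles = nrow(vals) / 3))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  ntri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  verts <- matrix(0, 3 * ntri, 3)
  for (i in seq_len(ntri)) {
    rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    readBin(con, "integer", n = 1, size = 2, endian = "little")
    verts[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
  }
  list(vertices = verts, n_triangles = ntri)
}

# total surface area of a triangle soup (list interface of read_stl)
stl_surface_area <- function(stl) {
  v <- stl$vertices
  idx <- seq(1, nrow(v), by = 3)
  sum(vapply(idx, function(i) {
    n <- cross3(v[i + 1, ] - v[i, ], v[i + 2, ] - v[i, ])
    sqrt(sum(n^2)) / 2
  }, numeric(1)))
}
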