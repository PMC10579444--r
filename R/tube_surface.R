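#' Triangulated tube surface of a coronary tree
#'
#' Sweeps a circle of the local radius along each branch centerline using
#' a twist-minimizing (parallel-transport) frame, producing one open-ended
#' triangulated tube per branch: `N` rings of `circumferential_samples`
#' vertices each, consecutive rings stitched with quads split into two
#' triangles. Intended for visualization and surface export; the
#' projection simulator works directly on the capsule representation and
#' does not depend on this mesh.
#'
#' @param tree a [coronary_tree()].
#' @param circumferential_samples vertices per ring (>= 3).
#' @return list with `vertices` (`V x 3`), `faces` (`F x 3`, 1-based
#'   vertex indices), and `branch` (branch index per vertex).
#' @export
tube_surface <- function(tree, circumferential_samples = 16L) {
  K <- as.integer(circumferential_samples)
  if (K < 3L) stop("need at least 3 circumferential samples")
  if (any(tree[, , 4] <= 0)) stop("all radii must be positive")
  M <- dim(tree)[1]; N <- dim(tree)[2]
  verts <- list(); faces <- list(); branch_id <- list()
  offset <- 0L
  ang <- 2 * pi * (seq_len(K) - 1) / K
  for (m in seq_len(M)) {
    p <- matrix(tree[m, , 1:3], N, 3)
    r <- tree[m, , 4]
    tang <- rbind(p[2, ] - p[1, ],
                  (p[-(1:2), , drop = FALSE] - p[1:(N - 2), , drop = FALSE]),
                  p[N, ] - p[N - 1, ])
    tang <- tang / sqrt(rowSums(tang^2))
    # parallel-transport frame
    u <- matrix(0, N, 3); v <- matrix(0, N, 3)
    ref <- if (abs(tang[1, 3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u[1, ] <- cross3(tang[1, ], ref); u[1, ] <- u[1, ] / vnorm(u[1, ])
    v[1, ] <- cross3(tang[1, ], u[1, ])
    for (i in 2:N) {
      axis <- cross3(tang[i - 1, ], tang[i, ])
      s <- vnorm(axis)
      if (s < 1e-12) { u[i, ] <- u[i - 1, ]; v[i, ] <- v[i - 1, ] }
      else {
        axis <- axis / s
        angr <- atan2(s, sum(tang[i - 1, ] * tang[i, ]))
        u[i, ] <- rotate_about(u[i - 1, ], axis, angr)
        v[i, ] <- cross3(tang[i, ], u[i, ])
      }
    }
    V <- matrix(0, N * K, 3)
    for (i in seq_len(N)) {
      ring <- p[rep(i, K), ] + r[i] * (outer(cos(ang), u[i, ]) +
                                         outer(sin(ang), v[i, ]))
      V[(i - 1) * K + seq_len(K), ] <- ring
    }
    # faces between ring i and i+1
    Fm <- matrix(0L, 2 * (N - 1) * K, 3)
    fi <- 1L
    for (i in seq_len(N - 1)) {
      a <- (i - 1L) * K + seq_len(K)
      b <- i * K + seq_len(K)
      a2 <- a[c(2:K, 1)]; b2 <- b[c(2:K, 1)]
      Fm[fi:(fi + K - 1L), ] <- cbind(a, b, b2)
      Fm[(fi + K):(fi + 2L * K - 1L), ] <- cbind(a, b2, a2)
      fi <- fi + 2L * K
    }
    verts[[m]] <- V
    faces[[m]] <- Fm + offset
    branch_id[[m]] <- rep(m, nrow(V))
    offset <- offset + nrow(V)
  }
  list(vertices = do.call(rbind, verts), faces = do.call(rbind, faces),
       branch = unlist(branch_id))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(x) sqrt(sum(x^2))

rotate_about <- function(x, axis, angle) {
  # Rodrigues rotation of vector x about unit axis
  x * cos(angle) + cross3(axis, x) * sin(angle) +
    axis * sum(axis * x) * (1 - cos(angle))
}

#' Write a tube surface as a legacy ASCII VTK polydata file
#'
#' @param surface result of [tube_surface()].
#' @param path output file path (conventionally `.vtk`).
#' @return `path`, invisibly.
#' @export
write_surface_vtk <- function(surface, path) {
  con <- file(path, "w"); on.exit(close(con))
  V <- surface$vertices; Fm <- surface$faces
  writeLines(c("# vtk DataFile Version 3.0", "vessel tube surface",
               "ASCII", "DATASET POLYDATA",
               paste("POINTS", nrow(V), "double")), con)
  utils::write.table(format(V, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(paste("POLYGONS", nrow(Fm), nrow(Fm) * 4), con)
  utils::write.table(cbind(3L, Fm - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
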