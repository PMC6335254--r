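# Shared fixtures and small independent oracles.

study_tab <- load_study_tables()
shape_k <- fit_shape_coefficients(study_tab)

# Brute-force point-in-polygon count: classify every pixel centre of a
# height x width grid with an even-odd ray test, independently of the
# scanline rasterizer it checks.
count_pixels_brute <- function(polygon, width, height) {
  n <- nrow(polygon)
  count <- 0L
  for (r in seq_len(height)) {
    for (c in seq_len(width)) {
      px <- c - 0.5; py <- r - 0.5
      inside <- FALSE
      j <- n
      for (i in seq_len(n)) {
        if ((polygon[i, 2] > py) != (polygon[j, 2] > py)) {
          xint <- polygon[i, 1] + (py - polygon[i, 2]) *
            (polygon[j, 1] - polygon[i, 1]) / (polygon[j, 2] - polygon[i, 2])
          if (px < xint) inside <- !inside
        }
        j <- i
      }
      if (inside) count <- count + 1L
    }
  }
  count
}

# TRUE when any two non-adjacent edges of the (open) polygon properly
# intersect; used to assert generated silhouettes are simple polygons.
polygon_self_intersects <- function(polygon) {
  n <- nrow(polygon)
  seg <- function(i) rbind(polygon[i, ], polygon[if (i == n) 1 else i + 1, ])
  orient <- function(p, q, r) {
    sign((q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1]))
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      a <- seg(i); b <- seg(j)
      if (orient(a[1, ], a[2, ], b[1, ]) * orient(a[1, ], a[2, ], b[2, ]) < 0 &&
          orient(b[1, ], b[2, ], a[1, ]) * orient(b[1, ], b[2, ], a[2, ]) < 0) {
        return(TRUE)
      }
    }
  }
  FALSE
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# Midranks derived by enumerating every tie-consistent ordering and
# averaging each element's position; independent oracle for rank-based
# correlation under ties (small n only).
midranks_by_enumeration <- function(x) {
  n <- length(x)
  perms <- pigspace:::all_perms(n)
  consistent <- apply(perms, 1, function(p) !is.unsorted(x[p]))
  perms <- perms[consistent, , drop = FALSE]
  ranks <- numeric(n)
  for (i in seq_len(n)) {
    # position of element i averaged over consistent orderings
    ranks[i] <- mean(apply(perms, 1, function(p) which(p == i)))
  }
  ranks
}

render_single <- function(sil, camera = camera_model()) {
  render_scene(scene_spec(camera, objects = list(sil)))
}
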