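# Geometry fixtures built in code: closed meshes and binary grids.

# unit-ish axis-aligned box mesh [0,s]^3 with outward winding (12 triangles)
cube_mesh <- function(side = 10, origin = c(0, 0, 0)) {
  v <- matrix(c(0,0,0, 1,0,0, 1,1,0, 0,1,0,
                0,0,1, 1,0,1, 1,1,1, 0,1,1), ncol = 3, byrow = TRUE)
  v <- sweep(v * side, 2, origin, "+")
  f <- matrix(c(1,3,2, 1,4,3,  5,6,7, 5,7,8,
                1,2,6, 1,6,5,  2,3,7, 2,7,6,
                3,4,8, 3,8,7,  4,1,5, 4,5,8), ncol = 3, byrow = TRUE)
  triangle_mesh(v, f)
}

# geodesic sphere by icosahedron subdivision, vertices projected to radius
icosphere <- function(radius = 1, subdiv = 3) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1,t,0), c(1,t,0), c(-1,-t,0), c(1,-t,0),
             c(0,-1,t), c(0,1,t), c(0,-1,-t), c(0,1,-t),
             c(t,0,-1), c(t,0,1), c(-t,0,-1), c(-t,0,1))
  f <- rbind(c(1,12,6), c(1,6,2), c(1,2,8), c(1,8,11), c(1,11,12),
             c(2,6,10), c(6,12,5), c(12,11,3), c(11,8,7), c(8,2,9),
             c(4,10,5), c(4,5,3), c(4,3,7), c(4,7,9), c(4,9,10),
             c(5,10,6), c(3,5,12), c(7,3,11), c(9,7,8), c(10,9,2))
  for (s in seq_len(subdiv)) {
    nf <- nrow(f)
    newf <- matrix(0L, 4 * nf, 3)
    mid <- new.env(parent = emptyenv())
    getmid <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      if (!is.null(mid[[k]])) return(mid[[k]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid[[k]] <- nrow(v)
      nrow(v)
    }
    for (i in seq_len(nf)) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- getmid(a, b); bc <- getmid(b, c_); ca <- getmid(c_, a)
      newf[4 * i - 3, ] <- c(a, ab, ca)
      newf[4 * i - 2, ] <- c(b, bc, ab)
      newf[4 * i - 1, ] <- c(c_, ca, bc)
      newf[4 * i, ] <- c(ab, bc, ca)
    }
    f <- newf
  }
  v <- v * radius / sqrt(rowSums(v^2))
  triangle_mesh(v, f)
}

# binary sphere occupancy grid centered at the origin
binary_sphere_grid <- function(radius = 5, voxel = 0.5, margin = 1) {
  spec <- grid_spec(rbind(rep(-radius - margin, 3), rep(radius + margin, 3)),
                    voxel_size = voxel, padding = 0)
  ax <- lapply(1:3, function(a)
    spec$origin[a] + (seq_len(spec$dims[a]) - 1) * voxel)
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  multichannel_grid(spec, shape = array(as.numeric(r2 <= radius^2),
                                        spec$dims))
}

# random binary grid on a fresh spec
random_binary_grid <- function(n = 16, p = 0.5, voxel = 1) {
  spec <- grid_spec(rbind(c(0, 0, 0), rep(n * voxel, 3)),
                    voxel_size = voxel, padding = 0)
  multichannel_grid(spec,
                    shape = array(as.numeric(runif(n^3) < p), spec$dims))
}

# small phantom used by property tests (fast to rasterize and segment)
small_phantom <- function(seed = 7, ...) {
  make_phantom(phantom_spec(dims = c(64, 64, 48), seed = seed, ...))
}
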