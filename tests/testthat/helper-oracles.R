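# Independent brute-force oracles used to validate the package's
# implementations. These deliberately avoid igraph and the package's own
# code paths: shortest paths are found by exhaustive simple-path
# enumeration, phi by expanding indicator vectors and calling cor().

# All simple paths between s and t in an adjacency matrix, by DFS.
enum_simple_paths <- function(adj, s, t) {
  paths <- list()
  rec <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (u in which(adj[v, ] > 0)) {
      if (!(u %in% path)) rec(c(path, u))
    }
  }
  rec(s)
  paths
}

# Degree, betweenness and closeness by exhaustive path enumeration.
# Returns a data frame in node order (names = rownames of adj).
oracle_centralities <- function(adj) {
  n <- nrow(adj)
  stopifnot(n >= 2, isTRUE(all(adj == t(adj))))
  dist <- matrix(Inf, n, n)
  bc_raw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq((s + 1), n)) {
      paths <- enum_simple_paths(adj, s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, 1L) - 1L
      d <- min(lens)
      dist[s, t] <- dist[t, s] <- d
      shortest <- paths[lens == d]
      sigma <- length(shortest)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(shortest, function(p) v %in% p, TRUE))
        bc_raw[v] <- bc_raw[v] + through / sigma
      }
    }
  }
  diag(dist) <- 0
  data.frame(
    node = rownames(adj),
    degree = rowSums(adj > 0),
    betweenness = bc_raw / ((n - 1) * (n - 2) / 2),
    closeness = (n - 1) / rowSums(dist),
    row.names = NULL
  )
}

oracle_global <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  for (s in seq_len(n - 1)) {
    for (t in seq((s + 1), n)) {
      paths <- enum_simple_paths(adj, s, t)
      if (length(paths) > 0) {
        dist[s, t] <- dist[t, s] <- min(vapply(paths, length, 1L)) - 1L
      }
    }
  }
  diag(dist) <- 0
  # local clustering: fraction of closed pairs among each node's neighbors
  cc <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    if (length(nb) < 2) return(0)
    pairs <- utils::combn(nb, 2)
    mean(adj[cbind(pairs[1, ], pairs[2, ])] > 0)
  }, 1.0)
  up <- dist[upper.tri(dist)]
  list(diameter = max(up), mspl = mean(up), acc = mean(cc))
}

# phi oracle: expand the 2x2 counts into indicator vectors, use cor().
oracle_phi <- function(N, N_i, N_j, N_ij) {
  x <- c(rep(1, N_ij), rep(1, N_i - N_ij), rep(0, N_j - N_ij),
         rep(0, N - N_i - N_j + N_ij))
  y <- c(rep(1, N_ij), rep(0, N_i - N_ij), rep(1, N_j - N_ij),
         rep(0, N - N_i - N_j + N_ij))
  stats::cor(x, y)
}

# Random connected labelled graph as an adjacency matrix (own BFS check).
random_connected_adj <- function(n, p = 0.5) {
  repeat {
    adj <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
      }
    }
    seen <- logical(n); queue <- 1L; seen[1] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] > 0 & !seen)
      seen[nb] <- TRUE; queue <- c(queue, nb)
    }
    if (all(seen)) {
      rownames(adj) <- colnames(adj) <- paste0("n", seq_len(n))
      return(adj)
    }
  }
}

adj_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# Hand-built claims table from per-patient code sets.
claims_from_sets <- function(sets, sex = "M", age = 30) {
  rows <- lapply(seq_along(sets), function(i) {
    codes <- sets[[i]]
    chunks <- split(codes, ceiling(seq_along(codes) / 5))
    do.call(rbind, lapply(chunks, function(ch) {
      ch <- c(ch, rep(NA_character_, 5 - length(ch)))
      data.frame(patient_id = sprintf("P%03d", i), sex = sex, age = age,
                 admission_date = as.Date("2005-06-01"),
                 dx1 = ch[1], dx2 = ch[2], dx3 = ch[3], dx4 = ch[4],
                 dx5 = ch[5])
    }))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

# category_profile object with prescribed counts, for proportion tests.
make_profile <- function(counts, total) {
  prof <- disease_categories()["label"]
  names(prof) <- "category"
  prof$count <- 0L
  prof$count[seq_along(counts)] <- as.integer(counts)
  structure(tibble::as_tibble(prof), total = total,
            class = c("category_profile", class(tibble::tibble())))
}

# prevalence_counts object with prescribed counts (bypasses claims).
make_counts <- function(N, diseases, pairs) {
  structure(list(N = N, diseases = diseases, pairs = pairs,
                 stratum = list(), node_level = 3),
            class = "prevalence_counts")
}
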