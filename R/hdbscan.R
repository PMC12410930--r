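# Hierarchical density-based clustering (HDBSCAN).
#
# Implements the standard pipeline: core distances at min_samples, mutual
# reachability distances, single-linkage hierarchy, condensed tree at
# min_cluster_size, and excess-of-mass (EOM) cluster selection. Points that
# detach from the hierarchy before any selected cluster are noise. O(n^2)
# in memory and time, adequate for event clouds of a few thousand points.
#
# Flat labeling adds a cluster-relative persistence rule: within each
# selected cluster, a point whose detachment density (the lambda at which
# it leaves the cluster) falls below `relative_density_min` times the
# cluster's median detachment density is noise. This makes a single
# population with sparse contamination behave sensibly -- the classic
# single-cluster pathology of plain EOM labeling -- while remaining
# self-normalizing in n and contamination level (densities are compared
# within the cluster, never on an absolute scale).

.hdbscan <- function(X, min_cluster_size, min_samples,
                     allow_single_cluster = TRUE,
                     relative_density_min = 0.2) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (min_cluster_size < 2) stop("min_cluster_size must be >= 2", call. = FALSE)
  if (min_cluster_size > n)
    stop("min_cluster_size exceeds the number of points", call. = FALSE)
  min_samples <- min(min_samples, n)

  d <- as.matrix(stats::dist(X))
  core <- apply(d, 1, function(r) sort(r, partial = min_samples)[min_samples])
  mr <- pmax(d, outer(core, core, pmax))
  hc <- stats::hclust(stats::as.dist(mr), method = "single")

  merge <- hc$merge
  lam_node <- 1 / pmax(hc$height, 1e-12)
  nn <- nrow(merge)

  # leaf members of every internal node (children rows precede parents)
  members <- vector("list", nn)
  msize <- integer(nn)
  node_members <- function(ch) if (ch < 0) -ch else members[[ch]]
  for (i in seq_len(nn)) {
    members[[i]] <- c(node_members(merge[i, 1]), node_members(merge[i, 2]))
    msize[i] <- length(members[[i]])
  }
  node_size <- function(ch) if (ch < 0) 1L else msize[ch]

  # condensed tree (iterative descent from the root merge)
  birth <- death <- stab <- numeric(0)
  parent <- integer(0)
  children <- list()
  fall_lambda <- rep(NA_real_, n)
  fall_cluster <- rep(NA_integer_, n)

  new_cluster <- function(b, par) {
    birth <<- c(birth, b); death <<- c(death, NA_real_)
    stab <<- c(stab, 0); parent <<- c(parent, par)
    children[[length(birth)]] <<- integer(0)
    length(birth)
  }
  root_id <- new_cluster(lam_node[nn], 0L)
  stack <- list(list(node = nn, cid = root_id))
  while (length(stack)) {
    task <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- task$node; cid <- task$cid
    lam <- lam_node[node]
    ch <- merge[node, ]
    sz <- c(node_size(ch[1]), node_size(ch[2]))
    big <- sz >= min_cluster_size
    drop_points <- function(chx) {
      pts <- node_members(chx)
      fall_lambda[pts] <<- lam
      fall_cluster[pts] <<- cid
    }
    if (all(big)) {
      death[cid] <- lam
      stab[cid] <- stab[cid] + sum(sz) * (lam - birth[cid])
      for (j in 1:2) {
        kid <- new_cluster(lam, cid)
        children[[cid]] <- c(children[[cid]], kid)
        stack[[length(stack) + 1L]] <- list(node = ch[j], cid = kid)
      }
    } else if (any(big)) {
      small <- ch[!big]; bigch <- ch[big]
      drop_points(small)
      stab[cid] <- stab[cid] + sum(sz[!big]) * (lam - birth[cid])
      stack[[length(stack) + 1L]] <- list(node = bigch, cid = cid)
    } else {
      drop_points(ch[1]); drop_points(ch[2])
      stab[cid] <- stab[cid] + sum(sz) * (lam - birth[cid])
      death[cid] <- lam
    }
  }

  # excess-of-mass selection, bottom-up (clusters created parent-first)
  ncl <- length(birth)
  selected <- rep(FALSE, ncl)
  score <- rep(0, ncl)
  deselect_subtree <- function(cid) {
    for (k in children[[cid]]) {
      selected[k] <<- FALSE
      deselect_subtree(k)
    }
  }
  for (cid in rev(seq_len(ncl))) {
    kids <- children[[cid]]
    if (!length(kids)) {
      selected[cid] <- TRUE
      score[cid] <- stab[cid]
    } else {
      cs <- sum(score[kids])
      if (stab[cid] > cs && (cid != root_id || allow_single_cluster)) {
        selected[cid] <- TRUE
        deselect_subtree(cid)
        score[cid] <- stab[cid]
      } else {
        score[cid] <- cs
      }
    }
  }
  if (!allow_single_cluster) selected[root_id] <- FALSE

  # assign each point to the first selected cluster on its ancestor chain
  labels <- integer(n)
  for (p in seq_len(n)) {
    cid <- fall_cluster[p]
    lab <- 0L
    while (!is.na(cid) && cid != 0L) {
      if (selected[cid]) { lab <- cid; break }
      cid <- parent[cid]
    }
    labels[p] <- lab
  }
  sel_ids <- which(selected)
  relab <- match(labels, sel_ids)    # NA -> noise
  labels <- ifelse(is.na(relab), -1L, relab)

  # cluster-relative persistence pruning
  if (relative_density_min > 0) {
    for (k in seq_along(sel_ids)) {
      in_k <- labels == k
      if (!any(in_k)) next
      lam_med <- stats::median(fall_lambda[in_k])
      labels[in_k & fall_lambda < relative_density_min * lam_med] <- -1L
    }
  }
  list(labels = labels, n_clusters = length(sel_ids),
       stability = stab[sel_ids])
}
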