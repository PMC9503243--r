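# Internal machinery shared by hill_climb() and tabu_search().  Nodes are
# integer-indexed; whitelist/blacklist live in logical matrices; local
# scores are cached by (child, parent-set bitmask).

make_score_env <- function(data, nodes, score, iss) {
  for (v in nodes) {
    if (!is.factor(data[[v]])) {
      stop("column '", v, "' is not discrete (factor)")
    }
  }
  int <- vapply(nodes, function(v) as.integer(data[[v]]), integer(nrow(data)))
  nlev <- vapply(nodes, function(v) nlevels(data[[v]]), integer(1))
  cache <- new.env(parent = emptyenv())
  n <- nrow(data)
  pow2 <- 2^(seq_along(nodes) - 1)
  function(child, parents) {
    key <- paste0(child, "_", sum(pow2[parents]))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    r <- nlev[[child]]
    if (!length(parents)) {
      counts <- matrix(tabulate(int[, child], nbins = r), ncol = 1L)
    } else {
      cfg <- rep(1L, n)
      mult <- 1L
      for (p in parents) {
        cfg <- cfg + (int[, p] - 1L) * mult
        mult <- mult * nlev[[p]]
      }
      counts <- matrix(tabulate(int[, child] + r * (cfg - 1L),
                                nbins = r * mult), nrow = r)
    }
    fc <- structure(list(child = nodes[child], parents = nodes[parents],
                         counts = counts, r = r, q = ncol(counts), n = n),
                    class = "family_counts")
    val <- local_score(score, fc, iss = iss)
    assign(key, val, envir = cache)
    val
  }
}

# TRUE when adding edge from -> to closes a cycle (i.e. `from` is reachable
# from `to`).  Integer DFS with a preallocated stack.
creates_cycle <- function(children, from, to, p) {
  if (from == to) return(TRUE)
  seen <- logical(p)
  stack <- integer(p)
  stack[1L] <- to
  top <- 1L
  seen[to] <- TRUE
  while (top > 0L) {
    v <- stack[top]
    top <- top - 1L
    for (w in children[[v]]) {
      if (w == from) return(TRUE)
      if (!seen[w]) {
        seen[w] <- TRUE
        top <- top + 1L
        stack[top] <- w
      }
    }
  }
  FALSE
}

prepare_search <- function(data, nodes, score, iss, constraints) {
  if (is.null(nodes)) nodes <- names(data)
  if (is.null(constraints)) constraints <- edge_constraints()
  p <- length(nodes)
  idx <- stats::setNames(seq_len(p), nodes)
  wl <- constraints$whitelist
  bl <- constraints$blacklist
  if (nrow(wl) && !all(wl %in% nodes)) stop("whitelist node not in `nodes`")
  bl <- bl[bl[, 1L] %in% nodes & bl[, 2L] %in% nodes, , drop = FALSE]
  wl_mat <- bl_mat <- matrix(FALSE, p, p)
  if (nrow(wl)) wl_mat[cbind(idx[wl[, 1L]], idx[wl[, 2L]])] <- TRUE
  if (nrow(bl)) bl_mat[cbind(idx[bl[, 1L]], idx[bl[, 2L]])] <- TRUE
  parents <- children <- rep(list(integer()), p)
  if (nrow(wl)) {
    for (i in seq_len(nrow(wl))) {
      f <- idx[[wl[i, 1L]]]
      t <- idx[[wl[i, 2L]]]
      parents[[t]] <- c(parents[[t]], f)
      children[[f]] <- c(children[[f]], t)
    }
  }
  st <- list(parents = parents, children = children)
  if (!is_acyclic(new_dag(nodes, wl, check_acyclic = FALSE))) {
    stop("whitelist contains a directed cycle")
  }
  list(nodes = nodes, p = p, local = make_score_env(data, nodes, score, iss),
       st = st, wl = wl_mat, bl = bl_mat)
}

# Best admissible move around the current graph.  Returns NULL or a list
# (type, from, to, delta, rank) where rank orders ties deterministically by
# (child, parent, move-type) name order; `skip` is a set of tabu move codes
# and `best_gap` enables the aspiration override.
move_code <- function(type_i, from, to, p) {
  (type_i - 1L) * p * p + (from - 1L) * p + to
}

scan_moves <- function(ps, st, max_parents, tabu_codes = integer(),
                       cur_score = NA_real_, best_score = NA_real_) {
  p <- ps$p
  local <- ps$local
  name_rank <- rank(ps$nodes, ties.method = "first")
  cur <- vapply(seq_len(p), function(v) local(v, st$parents[[v]]),
                numeric(1))
  best <- NULL
  consider <- function(type_i, from, to, delta) {
    rank_key <- c(delta, -name_rank[to], -name_rank[from], -type_i)
    if (length(tabu_codes) &&
        move_code(type_i, from, to, p) %in% tabu_codes) {
      aspiration <- !is.na(best_score) &&
        cur_score + delta > best_score + 1e-10
      if (!aspiration) return()
    }
    if (is.null(best)) {
      best <<- list(type_i = type_i, from = from, to = to, delta = delta,
                    key = rank_key)
      return()
    }
    cmp <- rank_key - best$key
    nz <- which(cmp != 0)
    if (length(nz) && cmp[nz[1L]] > 0) {
      best <<- list(type_i = type_i, from = from, to = to, delta = delta,
                    key = rank_key)
    }
  }
  for (to in seq_len(p)) {
    pa <- st$parents[[to]]
    for (from in seq_len(p)) {
      if (from == to) next
      present <- from %in% pa
      if (!present) {
        if (ps$bl[from, to]) next
        if (length(pa) >= max_parents) next
        if (creates_cycle(st$children, from, to, p)) next
        consider(1L, from, to, local(to, sort(c(pa, from))) - cur[to])
      } else if (!ps$wl[from, to]) {
        pa_less <- setdiff(pa, from)
        d_del <- local(to, pa_less) - cur[to]
        consider(2L, from, to, d_del)
        if (!ps$bl[to, from] &&
            length(st$parents[[from]]) < max_parents) {
          ch2 <- st$children
          ch2[[from]] <- setdiff(ch2[[from]], to)
          if (!creates_cycle(ch2, to, from, p)) {
            d_rev <- d_del +
              local(from, sort(c(st$parents[[from]], to))) - cur[from]
            consider(3L, from, to, d_rev)
          }
        }
      }
    }
  }
  best
}

apply_move_int <- function(st, mv) {
  from <- mv$from
  to <- mv$to
  if (mv$type_i == 1L) {
    st$parents[[to]] <- sort(c(st$parents[[to]], from))
    st$children[[from]] <- c(st$children[[from]], to)
  } else if (mv$type_i == 2L) {
    st$parents[[to]] <- setdiff(st$parents[[to]], from)
    st$children[[from]] <- setdiff(st$children[[from]], to)
  } else {
    st$parents[[to]] <- setdiff(st$parents[[to]], from)
    st$children[[from]] <- setdiff(st$children[[from]], to)
    st$parents[[from]] <- sort(c(st$parents[[from]], to))
    st$children[[to]] <- c(st$children[[to]], from)
  }
  st
}

state_to_dag <- function(st, nodes) {
  edges <- do.call(rbind, lapply(seq_along(nodes), function(v) {
    if (length(st$parents[[v]])) cbind(nodes[st$parents[[v]]], nodes[v])
    else NULL
  }))
  new_dag(nodes, edges)
}

state_score <- function(st, ps) {
  sum(vapply(seq_len(ps$p), function(v) ps$local(v, st$parents[[v]]),
             numeric(1)))
}

#' Greedy hill-climbing structure search
#'
#' Starts from the whitelist-only graph and repeatedly applies the
#' single-edge addition, deletion or reversal that most improves the chosen
#' decomposable score, subject to acyclicity and the whitelist/blacklist,
#' until no move improves.  Ties between equal-score moves break
#' deterministically by (child, parent, move-type) order, so results are
#' reproducible.
#'
#' @param data Data frame of factors.
#' @param score Score name, see [local_score()].
#' @param iss Imaginary sample size for `bde`/`bds`.
#' @param constraints An [edge_constraints()] object or `NULL`.
#' @param nodes Columns to include (default: all columns of `data`).
#' @param max_iter Maximum number of accepted moves.
#' @param max_parents Cap on the in-degree of any node.
#' @return The locally optimal [new_dag()].
#' @export
hill_climb <- function(data, score = "bic", iss = 1, constraints = NULL,
                       nodes = NULL, max_iter = 500L, max_parents = Inf) {
  ps <- prepare_search(data, nodes, score, iss, constraints)
  st <- ps$st
  for (iter in seq_len(max_iter)) {
    mv <- scan_moves(ps, st, max_parents)
    if (is.null(mv) || mv$delta <= 1e-10) break
    st <- apply_move_int(st, mv)
  }
  state_to_dag(st, ps$nodes)
}

#' Tabu structure search
#'
#' Hill-climbing that, at a local optimum, keeps moving: up to
#' `max_worsening` consecutive non-improving moves are accepted while the
#' inverses of the last `tabu_length` moves are forbidden (unless a move
#' improves on the best score seen, the usual aspiration rule).  The best
#' graph visited is returned.
#'
#' @inheritParams hill_climb
#' @param tabu_length Number of recent moves kept on the tabu list.
#' @param max_worsening Allowance of consecutive non-improving moves.
#' @param seed Optional integer; the search is deterministic, the seed is
#'   recorded for provenance only.
#' @return The best-scoring [new_dag()] visited.
#' @export
tabu_search <- function(data, score = "bic", iss = 1, constraints = NULL,
                        nodes = NULL, max_iter = 500L, tabu_length = 10L,
                        max_worsening = 100L, max_parents = Inf,
                        seed = NULL) {
  ps <- prepare_search(data, nodes, score, iss, constraints)
  p <- ps$p
  st <- ps$st
  best_st <- st
  best_score <- state_score(st, ps)
  cur_score <- best_score
  tabu <- integer()
  worsening <- 0L
  inverse_code <- function(mv) {
    switch(mv$type_i,
           move_code(2L, mv$from, mv$to, p),
           move_code(1L, mv$from, mv$to, p),
           move_code(3L, mv$to, mv$from, p))
  }
  for (iter in seq_len(max_iter)) {
    mv <- scan_moves(ps, st, max_parents, tabu_codes = tabu,
                     cur_score = cur_score, best_score = best_score)
    if (is.null(mv)) break
    if (mv$delta <= 1e-10) {
      worsening <- worsening + 1L
      if (worsening > max_worsening) break
    } else {
      worsening <- 0L
    }
    st <- apply_move_int(st, mv)
    cur_score <- cur_score + mv$delta
    tabu <- c(inverse_code(mv), tabu)
    if (length(tabu) > tabu_length) tabu <- tabu[seq_len(tabu_length)]
    if (cur_score > best_score + 1e-10) {
      best_score <- cur_score
      best_st <- st
    }
  }
  state_to_dag(best_st, ps$nodes)
}

#' Structural constraints of the survival 2-TBN
#'
#' Builds the whitelist/blacklist pair enforcing the temporal topology of
#' the survival network on the flat (unrolled) node set: the N/Q chain
#' between adjacent slices is forced present, covariates may connect among
#' themselves and into state nodes, and everything else (state into
#' covariate, within-slice state edges, non-adjacent or future-to-past
#' slices) is forbidden.
#'
#' @param covariates Character vector of covariate node names.
#' @param n_slices Number of slices `T`.
#' @param covariate_edges Allow covariate-to-covariate edges (default
#'   `TRUE`).
#' @return An [edge_constraints()] object.
#' @export
survival_constraints <- function(covariates, n_slices,
                                 covariate_edges = TRUE) {
  T <- n_slices
  states <- c(paste0("N@", seq_len(T)), paste0("Q@", seq_len(T)))
  wl <- NULL
  if (T >= 2L) {
    prev_n <- paste0("N@", seq_len(T - 1L))
    prev_q <- paste0("Q@", seq_len(T - 1L))
    cur_n <- paste0("N@", 2:T)
    cur_q <- paste0("Q@", 2:T)
    wl <- rbind(cbind(prev_n, cur_n), cbind(prev_q, cur_n),
                cbind(prev_n, cur_q), cbind(prev_q, cur_q))
  }
  all_nodes <- c(covariates, states)
  grid <- expand.grid(from = all_nodes, to = all_nodes,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, ]
  allowed <- function(from, to) {
    f_cov <- from %in% covariates
    t_cov <- to %in% covariates
    if (f_cov && t_cov) return(covariate_edges)
    if (f_cov && !t_cov) return(TRUE)          # covariate -> state
    if (!f_cov && t_cov) return(FALSE)         # state -> covariate
    # state -> state: only the adjacent-slice chain (whitelisted anyway)
    ft <- as.integer(sub("^[NQ]@", "", from))
    tt <- as.integer(sub("^[NQ]@", "", to))
    tt == ft + 1L
  }
  keep <- !mapply(allowed, grid$from, grid$to)
  bl <- as.matrix(grid[keep, , drop = FALSE])
  edge_constraints(whitelist = wl, blacklist = bl)
}
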