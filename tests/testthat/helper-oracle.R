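# Brute-force oracles, independent of the package's LP solver.

# All vertices of {A v = b, lb <= v <= ub} (finite bounds): every basic
# solution, i.e. every choice of rank(A) basic columns with the others
# fixed at a bound. A bounded LP attains its optimum at one of these.
enumerate_vertices <- function(A, b, lb, ub) {
  n <- ncol(A)
  qrt <- qr(t(A))
  r <- qrt$rank
  if (r > 0) A <- A[qrt$pivot[seq_len(r)], , drop = FALSE]
  b <- b[qrt$pivot[seq_len(r)]]
  verts <- list()
  add_if_feasible <- function(v) {
    if (all(v >= lb - 1e-8) && all(v <= ub + 1e-8))
      verts[[length(verts) + 1L]] <<- pmin(pmax(v, lb), ub)
  }
  if (r == 0) {
    grid <- as.matrix(expand.grid(rep(list(c(1, 2)), n)))
    for (g in seq_len(nrow(grid)))
      add_if_feasible(ifelse(grid[g, ] == 1, lb, ub))
    return(do.call(rbind, verts))
  }
  basis_sets <- utils::combn(n, r, simplify = FALSE)
  for (Bset in basis_sets) {
    AB <- A[, Bset, drop = FALSE]
    qb <- qr(AB)
    if (qb$rank < r) next
    Nset <- setdiff(seq_len(n), Bset)
    grid <- as.matrix(expand.grid(rep(list(c(1, 2)), length(Nset))))
    if (length(Nset) == 0) grid <- matrix(0, 1, 0)
    for (g in seq_len(nrow(grid))) {
      v <- numeric(n)
      if (length(Nset))
        v[Nset] <- ifelse(grid[g, ] == 1, lb[Nset], ub[Nset])
      rhs <- b - if (length(Nset))
        as.numeric(A[, Nset, drop = FALSE] %*% v[Nset]) else 0
      xB <- tryCatch(qr.coef(qb, rhs), error = function(e) NULL)
      if (is.null(xB) || any(is.na(xB))) next
      v[Bset] <- xB
      add_if_feasible(v)
    }
  }
  if (length(verts) == 0) return(NULL)
  do.call(rbind, verts)
}

# FVA by vertex enumeration: objective optimum, then per-reaction
# min/max over the vertices of the floor-constrained polytope.
vertex_fva <- function(model, fraction, reactions = NULL) {
  S <- as.matrix(stoich_matrix(model))
  rxn_ids <- model$reactions$id
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  if (is.null(reactions)) reactions <- rxn_ids
  iobj <- match(model$objective_id, rxn_ids)
  V0 <- enumerate_vertices(S, rep(0, nrow(S)), lb, ub)
  stopifnot(!is.null(V0))
  z_opt <- max(V0[, iobj])
  if (fraction > 0) {
    obj_row <- as.numeric(seq_along(rxn_ids) == iobj)
    sbig <- abs(z_opt) + sum(pmax(abs(lb), abs(ub))) + 1
    A <- rbind(cbind(S, 0), c(obj_row, -1))   # v_obj - s = f * z
    V <- enumerate_vertices(A, c(rep(0, nrow(S)), fraction * z_opt),
                            c(lb, 0), c(ub, sbig))
  } else V <- V0
  stopifnot(!is.null(V))
  idx <- match(reactions, rxn_ids)
  data.frame(reaction_id = reactions,
             min_flux = apply(V[, idx, drop = FALSE], 2, min),
             max_flux = apply(V[, idx, drop = FALSE], 2, max),
             stringsAsFactors = FALSE)
}

# Independent boolean-tree evaluator for GPR oracle tests: works on a
# nested list tree directly, without the package parser.
eval_tree <- function(tree, deleted) {
  if (is.character(tree)) return(!(tree %in% deleted))
  vals <- vapply(tree$args, eval_tree, TRUE, deleted = deleted)
  if (tree$op == "and") all(vals) else any(vals)
}

# Random GPR tree plus its rule string (built without the parser).
random_gpr_tree <- function(genes, depth = 2) {
  if (depth == 0 || (length(genes) > 1 && runif(1) < 0.3))
    return(sample(genes, 1))
  op <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  list(op = op, args = replicate(k, random_gpr_tree(genes, depth - 1),
                                 simplify = FALSE))
}

tree_to_string <- function(tree) {
  if (is.character(tree)) return(tree)
  paste0("(", paste(vapply(tree$args, tree_to_string, ""),
                    collapse = paste0(" ", tree$op, " ")), ")")
}
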