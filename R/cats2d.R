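#' Parse a molecule from SMILES
#'
#' Converts a SMILES string to a molecular graph via OpenBabel
#' (ChemmineOB/ChemmineR), with explicit hydrogens so hydrogen counts and
#' formal charges are available to the pharmacophore typing rules.  Only
#' heavy atoms enter the graph used for topological distances.
#'
#' @param smiles SMILES string of one connected molecule.
#' @param name Molecule name.
#' @return An object of class `odor_molecule`: `name`, `smiles`, `atoms`
#'   (tibble: `atom`, `element`, `charge`, `n_h`), `bonds` (heavy-atom
#'   tibble: `a1`, `a2`, `order`) and `dist`, the heavy-atom shortest-path
#'   bond-distance matrix.
#' @export
parse_molecule <- function(smiles, name = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  sdf_txt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(smiles, "\n"),
      options = data.frame(names = "h", args = "")
    )),
    error = function(e) ""
  )
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdf_txt, tf)
  sdf <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(tf)),
                  error = function(e) NULL)
  if (is.null(sdf) || length(sdf) == 0) {
    abort(sprintf("cannot parse SMILES '%s'", smiles),
          class = "odordisc_parse_error")
  }
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  element <- sub("_.*$", "", rownames(ab))
  # V2000 old-style charge codes: 1..3 = +3..+1, 5..7 = -1..-3
  code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, nrow(ab))
  charge <- dplyr::case_match(as.integer(code),
                              1L ~ 3L, 2L ~ 2L, 3L ~ 1L,
                              5L ~ -1L, 6L ~ -2L, 7L ~ -3L,
                              .default = 0L)
  bonds_all <- tibble(a1 = as.integer(bb[, "C1"]), a2 = as.integer(bb[, "C2"]),
                      order = as.integer(bb[, "C3"]))
  heavy <- which(element != "H")
  if (length(heavy) == 0) {
    abort(sprintf("'%s' has no heavy atom", smiles),
          class = "odordisc_parse_error")
  }
  is_h <- element == "H"
  n_h <- vapply(seq_along(element), function(a) {
    nb <- c(bonds_all$a2[bonds_all$a1 == a], bonds_all$a1[bonds_all$a2 == a])
    sum(is_h[nb])
  }, integer(1))

  remap <- match(seq_along(element), heavy)
  bonds <- bonds_all |>
    filter(!is_h[.data$a1] & !is_h[.data$a2]) |>
    mutate(a1 = remap[.data$a1], a2 = remap[.data$a2])
  g <- igraph::graph_from_data_frame(
    bonds[, c("a1", "a2")], directed = FALSE,
    vertices = data.frame(name = seq_along(heavy))
  )
  dist <- igraph::distances(g)
  if (any(!is.finite(dist))) {
    abort(sprintf("'%s' is a disconnected structure", smiles),
          class = "odordisc_parse_error")
  }
  structure(
    list(
      name = name,
      smiles = smiles,
      atoms = tibble(atom = seq_along(heavy), element = element[heavy],
                     charge = charge[heavy], n_h = n_h[heavy]),
      bonds = bonds,
      dist = dist
    ),
    class = "odor_molecule"
  )
}

#' @export
print.odor_molecule <- function(x, ...) {
  cat(sprintf("<odor_molecule> %s (%s): %d heavy atoms, %d bonds\n",
              x$name, x$smiles, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Assign pharmacophore atom types
#'
#' Types each heavy atom with zero or more of the five CATS pharmacophore
#' classes describing possible ligand-protein interactions:
#' \describe{
#'   \item{D (donor)}{O or N bearing at least one hydrogen.}
#'   \item{A (acceptor)}{any O; N not bonded to hydrogen and not positively
#'     charged.}
#'   \item{P (positive)}{atoms with positive formal charge; sp3 amine N
#'     (all single bonds, heavy neighbors only carbon, none of them a
#'     carbonyl-like carbon).}
#'   \item{N (negative)}{atoms with negative formal charge; acidic hydroxyl
#'     O attached to a C, S or P center that carries a double-bonded O
#'     (carboxylic, sulfonic, phosphoric acids).}
#'   \item{L (lipophilic)}{C or S whose neighbors are only C, S, H or
#'     halogens.}
#' }
#' Proprietary descriptor engines differ in the fine print of these rules;
#' this rule table is the package's declared dialect.
#'
#' @param mol An `odor_molecule` from [parse_molecule()].
#' @return A list, one character vector of types per heavy atom.
#' @export
assign_pharmacophore_types <- function(mol) {
  stopifnot(inherits(mol, "odor_molecule"))
  at <- mol$atoms
  halogens <- c("F", "Cl", "Br", "I")
  neighbors <- function(a) {
    rows <- mol$bonds$a1 == a | mol$bonds$a2 == a
    idx <- c(mol$bonds$a2[mol$bonds$a1 == a], mol$bonds$a1[mol$bonds$a2 == a])
    list(idx = idx, order = c(mol$bonds$order[mol$bonds$a1 == a],
                              mol$bonds$order[mol$bonds$a2 == a]))
  }
  has_double_o <- function(a) {
    nb <- neighbors(a)
    any(at$element[nb$idx] == "O" & nb$order == 2)
  }
  lapply(seq_len(nrow(at)), function(a) {
    el <- at$element[a]
    ch <- at$charge[a]
    nh <- at$n_h[a]
    nb <- neighbors(a)
    types <- character()
    if (el %in% c("O", "N") && nh >= 1) types <- c(types, "D")
    if (el == "O" || (el == "N" && nh == 0 && ch <= 0)) types <- c(types, "A")
    amine <- el == "N" && ch == 0 && all(nb$order == 1) &&
      all(at$element[nb$idx] == "C") &&
      !any(vapply(nb$idx, has_double_o, logical(1)))
    if (ch > 0 || amine) types <- c(types, "P")
    acidic_oh <- el == "O" && nh >= 1 &&
      any(at$element[nb$idx] %in% c("C", "S", "P") &
            vapply(nb$idx, has_double_o, logical(1)))
    if (ch < 0 || acidic_oh) types <- c(types, "N")
    if (el %in% c("C", "S") &&
        all(at$element[nb$idx] %in% c("C", "S", halogens))) {
      types <- c(types, "L")
    }
    types
  })
}

#' CATS2D descriptor names
#'
#' @param max_distance Largest topological distance counted.
#' @param pair_mode `"distinct"`: the 10 unordered pairs of distinct types
#'   (5*4/2), giving 90 descriptors at distances 0-8; `"full"`: all 15
#'   unordered pairs including same-type pairs (135 descriptors).
#' @return Character vector `CATS2D_<dd>_<XY>`, pair-major.
#' @export
cats2d_names <- function(max_distance = 8L, pair_mode = c("distinct", "full")) {
  pair_mode <- match.arg(pair_mode)
  types <- c("A", "D", "L", "N", "P")
  pairs <- utils::combn(types, 2, paste, collapse = "")
  if (pair_mode == "full") {
    pairs <- sort(c(pairs, paste0(types, types)))
  }
  as.vector(vapply(pairs, function(p) {
    sprintf("CATS2D_%02d_%s", 0:max_distance, p)
  }, character(max_distance + 1L)))
}

#' CATS2D pharmacophore-pair descriptor vector
#'
#' Counts, for every unordered pair of pharmacophore-typed atoms, how often
#' the pair occurs at each topological (shortest-path bond) distance from 0
#' to `max_distance`.  Two types on the same atom count as a pair at
#' distance 0.  With the default `pair_mode = "distinct"` and
#' `max_distance = 8` the vector has 10 pair types x 9 distances = 90
#' entries.
#'
#' @param mol An `odor_molecule`.
#' @inheritParams cats2d_names
#' @return Named integer vector of descriptor counts.
#' @export
cats2d <- function(mol, max_distance = 8L, pair_mode = c("distinct", "full")) {
  pair_mode <- match.arg(pair_mode)
  types <- assign_pharmacophore_types(mol)
  keys <- cats2d_names(max_distance, pair_mode)
  counts <- setNames(integer(length(keys)), keys)
  points <- tibble(
    atom = rep(seq_along(types), lengths(types)),
    type = unlist(types) %||% character()
  )
  n_pts <- nrow(points)
  if (n_pts >= 2) {
    for (i in seq_len(n_pts - 1)) {
      for (j in seq(i + 1, n_pts)) {
        d <- mol$dist[points$atom[i], points$atom[j]]
        if (d > max_distance) next
        pair <- paste(sort(c(points$type[i], points$type[j])), collapse = "")
        key <- sprintf("CATS2D_%02d_%s", d, pair)
        if (key %in% keys) counts[key] <- counts[key] + 1L
      }
    }
  }
  counts
}

#' Read a SMILES table
#'
#' Tab-separated lines `name<TAB>smiles[<TAB>label]`; `#` comments and
#' blank lines are skipped.
#'
#' @param path File path.
#' @return A tibble with columns `name`, `smiles` and (if present) `label`.
#' @export
read_smiles <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 2L)) {
    abort(sprintf("line %d: expected name<TAB>smiles[<TAB>label]",
                  which(n_fields < 2L)[1]),
          class = "odordisc_parse_error")
  }
  out <- tibble(
    name = vapply(fields, `[[`, character(1), 1),
    smiles = vapply(fields, `[[`, character(1), 2)
  )
  if (all(n_fields >= 3L)) {
    out$label <- vapply(fields, `[[`, character(1), 3)
  }
  out
}

#' The final distinctive / non-distinctive odorant structures
#'
#' SMILES for the 11 consensus odorants (4 distinctive, 7 non-distinctive),
#' curated from public chemical-structure databases and shipped as a
#' package fixture.
#'
#' @return A tibble `name`, `smiles`, `label`.
#' @export
final_odorants <- function() {
  read_smiles(system.file("extdata", "final_odorants.smi",
                          package = "odordisc", mustWork = TRUE))
}

#' CATS2D descriptor matrix for a molecule table
#'
#' @param molecules A tibble with columns `name`, `smiles` and optionally
#'   `label`.
#' @inheritParams cats2d_names
#' @return A tibble: `name` (and `label`), then one integer column per
#'   descriptor.
#' @export
cats2d_matrix <- function(molecules, max_distance = 8L,
                          pair_mode = c("distinct", "full")) {
  pair_mode <- match.arg(pair_mode)
  stopifnot(all(c("name", "smiles") %in% names(molecules)))
  desc <- purrr::map(seq_len(nrow(molecules)), function(i) {
    cats2d(parse_molecule(molecules$smiles[i], molecules$name[i]),
           max_distance, pair_mode)
  })
  out <- tibble(name = molecules$name)
  if ("label" %in% names(molecules)) out$label <- molecules$label
  bind_cols(out, as_tibble(do.call(rbind, desc)))
}

#' Filter a descriptor matrix by variance and correlation
#'
#' Drops descriptor columns with variance below `var_min`, then greedily
#' resolves remaining pairs with absolute Pearson correlation above
#' `cor_max`: while any such pair exists, the member of the worst pair with
#' the larger mean absolute correlation to all remaining descriptors is
#' removed (ties: the later column).  The procedure is deterministic.
#'
#' @param desc A descriptor tibble from [cats2d_matrix()] (non-numeric
#'   columns such as `name`/`label` are passed through untouched).
#' @param var_min Minimum variance kept.
#' @param cor_max Maximum absolute pairwise correlation kept.
#' @return The reduced tibble; attributes `"dropped_variance"` and
#'   `"dropped_correlation"` list the removed descriptor names.
#' @export
filter_descriptors <- function(desc, var_min = 0.2, cor_max = 0.75) {
  is_num <- vapply(desc, is.numeric, logical(1))
  meta <- desc[, !is_num, drop = FALSE]
  m <- as.matrix(desc[, is_num, drop = FALSE])
  if (nrow(m) < 2L) {
    abort("need at least two molecules", class = "odordisc_data_error")
  }
  vars <- apply(m, 2, var)
  dropped_var <- colnames(m)[vars < var_min]
  m <- m[, vars >= var_min, drop = FALSE]
  dropped_cor <- character()
  while (ncol(m) >= 2L) {
    cm <- abs(cor(m))
    diag(cm) <- 0
    if (max(cm) <= cor_max) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    mean_abs <- colMeans(abs(cor(m)))
    drop_idx <- if (mean_abs[worst["row"]] > mean_abs[worst["col"]]) {
      worst[["row"]]
    } else if (mean_abs[worst["row"]] < mean_abs[worst["col"]]) {
      worst[["col"]]
    } else {
      max(worst)
    }
    dropped_cor <- c(dropped_cor, colnames(m)[drop_idx])
    m <- m[, -drop_idx, drop = FALSE]
  }
  if (ncol(m) == 0L) {
    abort(sprintf(
      "all descriptors removed (variance < %g: %d, correlation > %g: %d)",
      var_min, length(dropped_var), cor_max, length(dropped_cor)),
      class = "odordisc_data_error")
  }
  structure(bind_cols(meta, as_tibble(m)),
            dropped_variance = dropped_var,
            dropped_correlation = dropped_cor)
}

#' Leave-one-out tree-ensemble classification of odor sets
#'
#' Classifies molecules (e.g. distinctive versus non-distinctive odorants)
#' from their descriptors by leave-one-out cross-validation, the scheme of
#' choice at these very small sample sizes: each molecule is scored by a
#' forest trained on all the others, and the collected scores give one
#' AUC-ROC.  `model = "forest"` is a random forest (`mtry = sqrt(p)`);
#' `model = "bagged_trees"` is bagged CART (`mtry = p`, i.e. every tree
#' sees all descriptors).  With `permute = TRUE`, labels are shuffled
#' before each of `n_cycles` full LOO cycles -- the negative control.
#'
#' @param desc Descriptor tibble (non-numeric columns ignored) or matrix.
#' @param labels Two-level factor (or character) of class labels; the
#'   second level is scored as the positive class.
#' @param model `"forest"` or `"bagged_trees"`.
#' @param n_trees Trees per ensemble.
#' @param permute Shuffle labels before each LOO cycle.
#' @param n_cycles Number of LOO cycles (only useful with `permute`).
#' @param seed Optional seed for reproducibility.
#' @return An object of class `loo_result`: `auc` (vector, one per cycle),
#'   `auc_median`, `scores` (last cycle's LOO scores), `importance` (mean
#'   Gini importance over folds of the last cycle), `model`, `permuted`.
#' @export
loo_classify <- function(desc, labels, model = c("forest", "bagged_trees"),
                         n_trees = 500L, permute = FALSE, n_cycles = 1L,
                         seed = NULL) {
  model <- match.arg(model)
  is_num <- vapply(as.data.frame(desc), is.numeric, logical(1))
  x <- as.matrix(as.data.frame(desc)[, is_num, drop = FALSE])
  labels <- factor(labels)
  if (nlevels(labels) != 2L) {
    abort("need exactly two classes", class = "odordisc_data_error")
  }
  if (min(table(labels)) < 2L) {
    abort("need at least two molecules per class",
          class = "odordisc_data_error")
  }
  mtry <- if (model == "bagged_trees") ncol(x) else
    max(1L, floor(sqrt(ncol(x))))
  run_cycle <- function(y) {
    scores <- numeric(nrow(x))
    imp <- numeric(ncol(x))
    for (i in seq_len(nrow(x))) {
      y_tr <- y[-i]
      # class-balanced per-tree bootstrap: leaving one molecule out skews
      # the already unequal class sizes, which would bias each vote toward
      # the majority class and drag the permuted-label control below 0.5
      rf <- randomForest::randomForest(
        x[-i, , drop = FALSE], y_tr, ntree = n_trees, mtry = mtry,
        strata = y_tr, sampsize = rep(min(table(y_tr)), 2L)
      )
      scores[i] <- predict(rf, x[i, , drop = FALSE],
                           type = "prob")[, levels(y)[2]]
      imp <- imp + rf$importance[, "MeanDecreaseGini"]
    }
    auc <- as.numeric(pROC::auc(response = y, predictor = scores,
                                levels = levels(y), direction = "<",
                                quiet = TRUE))
    list(auc = auc, scores = scores, importance = imp / nrow(x))
  }
  body <- function() {
    cycles <- lapply(seq_len(n_cycles), function(cycle) {
      y <- if (permute) sample(labels) else labels
      run_cycle(y)
    })
    last <- cycles[[length(cycles)]]
    structure(
      list(
        auc = vapply(cycles, `[[`, numeric(1), "auc"),
        auc_median = median(vapply(cycles, `[[`, numeric(1), "auc")),
        scores = tibble(name = if ("name" %in% names(desc)) desc$name else
          as.character(seq_len(nrow(x))),
          label = labels, score = last$scores),
        importance = tibble(descriptor = colnames(x),
                            importance = last$importance) |>
          arrange(dplyr::desc(.data$importance)),
        model = model,
        permuted = permute
      ),
      class = "loo_result"
    )
  }
  if (!is.null(seed)) withr::with_seed(seed, body()) else body()
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("<loo_result> %s%s: median LOO AUC %.3f over %d cycle(s)\n",
              x$model, if (x$permuted) " [permuted labels]" else "",
              x$auc_median, length(x$auc)))
  invisible(x)
}

#' @rdname loo_classify
#' @param x A `loo_result`.
#' @param ... Unused.
#' @method glance loo_result
#' @export
glance.loo_result <- function(x, ...) {
  tibble(model = x$model, permuted = x$permuted, n_cycles = length(x$auc),
         auc_median = x$auc_median)
}
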