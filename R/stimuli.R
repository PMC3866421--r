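#' Default basic-to-global category taxonomy
#'
#' The 26 basic-level object categories used throughout the package, each
#' mapped to one of the four global-level categories (humans, animals,
#' vehicles, furniture) classically used in infant categorization work.
#'
#' @return Named character vector: names are basic-level categories, values
#'   their global-level parents.
#' @export
#' @examples
#' table(default_taxonomy())
default_taxonomy <- function() {
  c(
    male = "humans", female = "humans",
    dog = "animals", cat = "animals", rabbit = "animals", horse = "animals",
    elephant = "animals", giraffe = "animals", cow = "animals",
    squirrel = "animals", fish = "animals", eagle = "animals",
    songbird = "animals", duck = "animals",
    bicycle = "vehicles", forklift = "vehicles", bus = "vehicles",
    car = "vehicles", plane = "vehicles", ship = "vehicles",
    desk = "furniture", table = "furniture", bed = "furniture",
    sofa = "furniture", chest_of_drawers = "furniture", chair = "furniture"
  )
}

# Feature indices holding the facial measurements (eye separation, face
# length, face width) when the default 18-feature layout is used.
FACIAL_FEATURES <- 16:18
FACED_GLOBALS <- c("humans", "animals")

#' Describe a synthetic stimulus corpus
#'
#' A stimulus design specifies the hierarchical generative process that stands
#' in for the photograph-derived feature measurements of the original corpus:
#' one latent anchor per global-level category, basic-level generating
#' prototypes scattered around their anchor with spread `sigma_global`, and
#' exemplars jittered around their generating prototype with spread
#' `sigma_basic`. All feature values are clipped to `[0, 1]`.
#'
#' @param n_exemplars Exemplars per basic-level category (default 8).
#' @param n_features Length of each feature vector (default 18).
#' @param taxonomy Named character vector mapping basic-level categories to
#'   global-level categories; defaults to [default_taxonomy()].
#' @param sigma_global Spread of basic-level generating prototypes around
#'   their global anchor (default 0.15).
#' @param sigma_basic Exemplar jitter around the generating prototype
#'   (default 0.05).
#' @param sigma_basic_overrides Optional named numeric vector of per-category
#'   jitter values overriding `sigma_basic`.
#' @param faceless_near_zero If `TRUE` (default) the facial features of
#'   categories outside `faced_globals` are drawn near 0, mirroring the
#'   absence of faces on vehicles and furniture. Only applies when
#'   `n_features` is 18.
#' @param faced_globals Global categories whose members carry facial features.
#' @param seed Integer seed; generation is fully reproducible per seed.
#'
#' @return An object of class `stimulus_design`.
#' @seealso [generate_stimulus_set()]
#' @export
stimulus_design <- function(n_exemplars = 8,
                            n_features = 18,
                            taxonomy = default_taxonomy(),
                            sigma_global = 0.15,
                            sigma_basic = 0.05,
                            sigma_basic_overrides = NULL,
                            faceless_near_zero = TRUE,
                            faced_globals = FACED_GLOBALS,
                            seed = 1L) {
  if (length(taxonomy) < 1L || is.null(names(taxonomy)) ||
      anyNA(taxonomy) || any(!nzchar(taxonomy)))
    stop_config("taxonomy must map each basic-level category to a non-empty global-level category")
  if (anyDuplicated(names(taxonomy)))
    stop_config("taxonomy contains duplicated basic-level categories")
  if (!is.null(sigma_basic_overrides)) {
    bad <- setdiff(names(sigma_basic_overrides), names(taxonomy))
    if (length(bad))
      stop_config("sigma_basic_overrides names unknown categories: %s",
                  paste(bad, collapse = ", "))
  }
  design <- structure(list(
    n_basic = length(taxonomy),
    n_exemplars = check_count(n_exemplars, "n_exemplars"),
    n_features = check_count(n_features, "n_features"),
    taxonomy = taxonomy,
    sigma_global = check_number(sigma_global, "sigma_global", min = 0),
    sigma_basic = check_number(sigma_basic, "sigma_basic", min = 0),
    sigma_basic_overrides = sigma_basic_overrides,
    faceless_near_zero = isTRUE(faceless_near_zero),
    faced_globals = faced_globals,
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  ), class = "stimulus_design")
  design
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Generate a synthetic stimulus set
#'
#' Draws a full corpus from a [stimulus_design()]: `n_basic * n_exemplars`
#' objects, each an `n_features`-dimensional feature vector in `[0, 1]`, with
#' tight within-basic-category similarity and looser within-global-category
#' similarity. Empirical category prototypes are the feature means of each
#' category's exemplars (computed by [compute_prototypes()]), and are not
#' themselves members of the exemplar set.
#'
#' @param design A `stimulus_design`.
#' @return An object of class `stimulus_set` with elements `exemplars` (a
#'   data frame with columns `id`, `basic_category`, `global_category`,
#'   `f1..f<n>`), `prototypes` (matrix, one row per basic category),
#'   `taxonomy`, `label_vocab_basic`, `label_vocab_global`, and `design`.
#' @export
#' @examples
#' set <- generate_stimulus_set(stimulus_design(seed = 42))
#' nrow(set$exemplars)   # 208
#' nrow(set$prototypes)  # 26
generate_stimulus_set <- function(design = stimulus_design()) {
  if (!inherits(design, "stimulus_design"))
    stop_config("design must be created with stimulus_design()")
  tax <- design$taxonomy
  basics <- names(tax)
  globals <- unique(unname(tax))
  p <- design$n_features
  facial <- design$faceless_near_zero && p == 18L

  rows <- with_local_seed(design$seed, {
    anchors <- vapply(globals, function(g) stats::runif(p, 0.2, 0.8), numeric(p))
    out <- vector("list", length(basics))
    for (i in seq_along(basics)) {
      b <- basics[[i]]
      g <- tax[[b]]
      proto <- clip01(anchors[, g] + stats::rnorm(p, 0, design$sigma_global))
      if (facial && !(g %in% design$faced_globals))
        proto[FACIAL_FEATURES] <- stats::runif(length(FACIAL_FEATURES), 0, 0.05)
      sb <- design$sigma_basic_overrides[[b]] %||% design$sigma_basic
      ex <- matrix(0, design$n_exemplars, p)
      for (k in seq_len(design$n_exemplars))
        ex[k, ] <- clip01(proto + stats::rnorm(p, 0, sb))
      out[[i]] <- ex
    }
    out
  })

  feat <- do.call(rbind, rows)
  colnames(feat) <- paste0("f", seq_len(p))
  exemplars <- data.frame(
    id = paste(rep(basics, each = design$n_exemplars),
               rep(seq_len(design$n_exemplars), times = length(basics)),
               sep = "_"),
    basic_category = rep(basics, each = design$n_exemplars),
    global_category = rep(unname(tax), each = design$n_exemplars),
    stringsAsFactors = FALSE
  )
  exemplars <- cbind(exemplars, as.data.frame(feat))

  set <- structure(list(
    exemplars = exemplars,
    prototypes = NULL,
    taxonomy = tax,
    label_vocab_basic = basics,
    label_vocab_global = globals,
    design = design
  ), class = "stimulus_set")
  set$prototypes <- compute_prototypes(set)
  set
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf(
    "Stimulus set: %d exemplars, %d basic-level categories (%d global), %d features\n",
    nrow(x$exemplars), length(x$label_vocab_basic),
    length(x$label_vocab_global), n_features(x)))
  invisible(x)
}

n_features <- function(set) sum(startsWith(names(set$exemplars), "f"))

#' Extract the exemplar feature matrix
#'
#' @param set A `stimulus_set`.
#' @return Numeric matrix, one row per exemplar (rownames are stimulus ids).
#' @export
feature_matrix <- function(set) {
  fcols <- grep("^f[0-9]+$", names(set$exemplars), value = TRUE)
  m <- as.matrix(set$exemplars[fcols])
  rownames(m) <- set$exemplars$id
  m
}

#' Compute basic-level category prototypes
#'
#' The prototype of a category is the element-wise arithmetic mean of its
#' exemplars' feature vectors; prototypes are held out of the exemplar set.
#'
#' @param set A `stimulus_set` (its `exemplars` component is used).
#' @return Matrix with one row per basic-level category (in taxonomy order)
#'   and one column per feature.
#' @export
compute_prototypes <- function(set) {
  ex <- set$exemplars
  basics <- names(set$taxonomy)
  missing <- setdiff(basics, unique(ex$basic_category))
  if (length(missing))
    stop_config("category with no exemplars: %s", paste(missing, collapse = ", "))
  feat <- feature_matrix(set)
  g <- factor(ex$basic_category, levels = basics)
  proto <- rowsum(feat, g) / as.vector(table(g))
  rownames(proto) <- basics
  proto
}

# ---------------------------------------------------------------------------
# delimited table IO

#' Write a stimulus set to a comma-separated table
#'
#' Header `id,basic_category,global_category,f1,...,f<n>`; feature values are
#' printed with 17 significant digits so that a write/read round trip is
#' exact.
#'
#' @param set A `stimulus_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stimulus_table <- function(set, path) {
  feat <- feature_matrix(set)
  txt <- apply(feat, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  lines <- c(
    paste(c("id", "basic_category", "global_category", colnames(feat)),
          collapse = ","),
    paste(set$exemplars$id, set$exemplars$basic_category,
          set$exemplars$global_category, txt, sep = ",")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a stimulus set from a comma-separated table
#'
#' Validates feature bounds and taxonomy consistency row by row; prototypes
#' are recomputed from the exemplars on load.
#'
#' @param path File written by [write_stimulus_table()] or of the same layout.
#' @return A `stimulus_set`.
#' @export
read_stimulus_table <- function(path) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) <= 1L) stop_config("no stimuli in %s", path)
  header <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  fcols <- grep("^f[0-9]+$", header, value = TRUE)
  expected <- c("id", "basic_category", "global_category", fcols)
  if (length(fcols) < 1L || !identical(header, expected))
    stop_config("bad header: expected id,basic_category,global_category,f1,...")
  p <- length(fcols)

  n <- length(lines) - 1L
  ids <- character(n); basic <- character(n); glob <- character(n)
  feat <- matrix(NA_real_, n, p, dimnames = list(NULL, fcols))
  for (i in seq_len(n)) {
    parts <- strsplit(lines[[i + 1L]], ",", fixed = TRUE)[[1L]]
    if (length(parts) != p + 3L)
      stop_config("row %d: expected %d columns, found %d", i, p + 3L, length(parts))
    vals <- suppressWarnings(as.numeric(parts[-(1:3)]))
    if (anyNA(vals))
      stop_config("row %d: non-numeric feature value", i)
    if (any(vals < 0 | vals > 1))
      stop_config("row %d: feature value outside [0, 1]", i)
    ids[[i]] <- parts[[1L]]; basic[[i]] <- parts[[2L]]; glob[[i]] <- parts[[3L]]
    feat[i, ] <- vals
  }
  # each basic category must map to a single global category
  tax_pairs <- unique(data.frame(basic = basic, global = glob))
  if (anyDuplicated(tax_pairs$basic)) {
    dup <- tax_pairs$basic[duplicated(tax_pairs$basic)][[1L]]
    stop_config("category '%s' is mapped to more than one global category", dup)
  }
  tax <- stats::setNames(tax_pairs$global, tax_pairs$basic)

  exemplars <- cbind(
    data.frame(id = ids, basic_category = basic, global_category = glob,
               stringsAsFactors = FALSE),
    as.data.frame(feat)
  )
  set <- structure(list(
    exemplars = exemplars,
    prototypes = NULL,
    taxonomy = tax,
    label_vocab_basic = names(tax),
    label_vocab_global = unique(unname(tax)),
    design = NULL
  ), class = "stimulus_set")
  set$prototypes <- compute_prototypes(set)
  set
}
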