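# JSON serialization of complete simulation state. The document is
# versioned, human-readable (stable, sorted top-level keys), and numbers
# are emitted at full precision so that a resumed run continues bitwise
# identically -- including stochastic runs, because the named RNG stream
# states are part of the document. Callbacks (custom potentials, reactions,
# events) are serialized by registered name only: JSON is data, and import
# requires the same names in the callback registry.

STATE_SCHEMA_VERSION <- 1L

#' Serialize a universe to JSON
#'
#' Captures the complete simulation state between steps: universe header,
#' RNG stream states, type table, the full particle slot table (dead slots
#' included, so memory order and hence floating-point summation order are
#' reproduced exactly on import), clusters, bonded tables, bindings,
#' explicit forces, flux rules, reactions and events (the latter by
#' registered name).
#'
#' @param u a [universe]
#' @return a JSON string
#' @export
to_json <- function(u) {
  n <- u$n_slots
  doc <- list(
    schema_version = STATE_SCHEMA_VERSION,
    universe = list(
      dims = u$dims, boundary = u$boundary, cutoff = u$cutoff, dt = u$dt,
      time = u$time, step_count = u$step_count, seed = u$seed,
      n_substeps = u$n_substeps, confine_axis = u$confine_axis,
      overdamped_cap = u$overdamped_cap,
      id_next = u$id_next, cluster_id_next = u$cluster_id_next,
      bond_id_next = u$bond_id_next, event_id_next = u$event_id_next,
      clamp_warnings = u$clamp_warnings,
      potential_energy = u$potential_energy),
    rng = u$rng,
    types = lapply(u$type_names, function(nm) {
      t <- u$types[[nm]]
      list(name = t$name, mass = t$mass, radius = t$radius,
           dynamics = t$dynamics, species_names = as.list(t$species_names),
           frozen_default = t$frozen_default)
    }),
    species = as.list(u$species),
    particles = list(
      id = u$id[seq_len(n)], type = u$type_names[u$type_id[seq_len(n)]],
      alive = u$alive[seq_len(n)], frozen = u$frozen[seq_len(n)],
      mass = u$mass[seq_len(n)], radius = u$radius[seq_len(n)],
      cluster_id = u$cluster_id[seq_len(n)],
      pos = u$pos[seq_len(n), , drop = FALSE],
      vel = u$vel[seq_len(n), , drop = FALSE],
      state = u$state[seq_len(n), , drop = FALSE]),
    clusters = unname(lapply(u$clusters, function(cl) {
      list(id = cl$id, members = as.list(cl$members),
           children = as.list(cl$children), parent = cl$parent)
    })),
    bonds = .bonded_to_list(u$bonds),
    angles = .bonded_to_list(u$angles),
    dihedrals = .bonded_to_list(u$dihedrals),
    bindings = lapply(u$bindings, function(b) {
      list(type_a = b$a_name, type_b = b$b_name, mode = b$mode,
           potential = pot_to_list(b$pot))
    }),
    explicit_forces = lapply(u$explicit, function(x) {
      list(type = x$type_name, force = force_to_list(x$force))
    }),
    flux_rules = lapply(u$flux_rules, function(r) {
      list(species = r$species, type_a = r$a_name, type_b = r$b_name,
           kind = r$kind, k = r$k, r_cutoff = r$r_cutoff,
           direction = r$direction)
    }),
    reactions = lapply(u$reactions, function(r) {
      if (is.null(r$name)) stop("reactions must carry a registry `name` to be serialized")
      list(type = r$type_name, name = r$name)
    }),
    events = lapply(u$events, function(e) {
      if (is.null(e$name)) stop("events must carry a registry `name` to be serialized")
      list(id = e$id, period = e$period, name = e$name)
    })
  )
  doc <- doc[order(names(doc))]
  # 17 significant digits guarantee exact double round-trip
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), na = "null",
                   null = "null", pretty = TRUE)
}

.bonded_to_list <- function(b) {
  items <- lapply(seq_along(b$id), function(n) {
    it <- list(id = b$id[n])
    for (e in b$endpoints) it[[e]] <- b[[e]][n]
    it$potential <- pot_to_list(b$pot[[n]])
    it$dissociation_energy <- b$diss[n]
    it$energy <- b$energy[n]
    it
  })
  items
}

#' Restore a universe from JSON
#'
#' Rebuilds the universe exactly as exported by [to_json()]; the subsequent
#' trajectory of the imported universe is bitwise identical to continuing
#' the original. Unknown schema versions, missing sections, dangling ids
#' and unresolvable callback names produce descriptive errors.
#'
#' @param txt a JSON string (or path to a JSON file)
#' @return a [universe]
#' @export
from_json <- function(txt) {
  if (length(txt) == 1 && !grepl("[{]", txt) && file.exists(txt)) {
    txt <- paste(readLines(txt, warn = FALSE), collapse = "\n")
  }
  doc <- jsonlite::fromJSON(txt, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  for (sec in c("schema_version", "universe", "rng", "types", "species",
                "particles", "clusters", "bonds", "angles", "dihedrals",
                "bindings", "explicit_forces", "flux_rules", "reactions",
                "events")) {
    if (!sec %in% names(doc)) stop(sprintf("state document is missing section '%s'", sec))
  }
  if (doc$schema_version != STATE_SCHEMA_VERSION) {
    stop(sprintf("unsupported state schema version %s", doc$schema_version))
  }
  h <- doc$universe
  u <- universe(dims = unlist(h$dims), cutoff = h$cutoff, dt = h$dt,
                boundary = unlist(h$boundary), seed = h$seed,
                n_substeps = h$n_substeps, confine_axis = h$confine_axis,
                overdamped_cap = if (is.null(h$overdamped_cap)) Inf
                                 else as.numeric(h$overdamped_cap))
  for (nm in names(doc$rng)) u$rng[[nm]] <- as.integer(doc$rng[[nm]])
  for (t in doc$types) {
    register_type(u, particle_type(t$name, mass = t$mass, radius = t$radius,
                                   dynamics = t$dynamics,
                                   species = unlist(t$species_names),
                                   frozen = t$frozen_default))
  }
  if (!identical(as.character(unlist(doc$species)), character(0)) &&
      !identical(unlist(doc$species), u$species)) {
    # species order must match the exporting universe's global table
    u$species <- as.character(unlist(doc$species))
    u$state <- matrix(0, u$cap, length(u$species))
  }
  p <- doc$particles
  n <- length(p$id)
  if (n > 0) {
    .ensure_capacity(u, n)
    u$n_slots <- n
    u$id[1:n] <- as.integer(p$id)
    u$type_id[1:n] <- match(unlist(p$type), u$type_names)
    if (any(is.na(u$type_id[1:n]))) stop("particle references an unknown type")
    u$alive[1:n] <- as.logical(p$alive)
    u$frozen[1:n] <- as.logical(p$frozen)
    u$mass[1:n] <- as.numeric(p$mass)
    u$radius[1:n] <- as.numeric(p$radius)
    cid <- p$cluster_id
    cid[vapply(cid, is.null, TRUE)] <- NA_integer_
    u$cluster_id[1:n] <- as.integer(unlist(cid))
    u$pos[1:n, ] <- .as_mat(p$pos, n, 3)
    u$vel[1:n, ] <- .as_mat(p$vel, n, 3)
    if (length(u$species)) u$state[1:n, ] <- .as_mat(p$state, n, length(u$species))
    u$id2slot <- rep(NA_integer_, h$id_next)
    u$id2slot[u$id[1:n][u$alive[1:n]] + 1L] <- which(u$alive[1:n])
  }
  u$id_next <- as.integer(h$id_next)
  u$cluster_id_next <- as.integer(h$cluster_id_next)
  u$bond_id_next <- as.integer(h$bond_id_next)
  u$event_id_next <- as.integer(h$event_id_next)
  u$clamp_warnings <- as.integer(h$clamp_warnings)
  u$potential_energy <- as.numeric(h$potential_energy)
  u$time <- as.numeric(h$time)
  u$step_count <- as.integer(h$step_count)
  for (cl in doc$clusters) {
    u$clusters[[as.character(cl$id)]] <- list(
      id = as.integer(cl$id), members = as.integer(unlist(cl$members)),
      children = as.integer(unlist(cl$children)),
      parent = if (is.null(cl$parent)) NA_integer_ else as.integer(cl$parent))
  }
  if (length(doc$clusters)) .refresh_top_clusters(u)
  .bonded_from_list(u, "bonds", doc$bonds)
  .bonded_from_list(u, "angles", doc$angles)
  .bonded_from_list(u, "dihedrals", doc$dihedrals)
  for (b in doc$bindings) {
    bind_potential(u, b$type_a, b$type_b, pot_from_list(b$potential), b$mode)
  }
  for (x in doc$explicit_forces) bind_force(u, x$type, force_from_list(x$force))
  for (r in doc$flux_rules) {
    add_flux_rule(u, r$species, r$type_a, r$type_b, r$kind, r$k, r$r_cutoff,
                  r$direction)
  }
  for (r in doc$reactions) add_reaction(u, r$type, get_callback(r$name), name = r$name)
  for (e in doc$events) {
    u$events <- c(u$events, list(list(id = as.integer(e$id),
                                      period = as.integer(e$period),
                                      fn = get_callback(e$name), name = e$name)))
  }
  u
}

.as_mat <- function(x, n, m) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    x
  } else {
    matrix(as.numeric(unlist(x)), n, m, byrow = TRUE)
  }
}

.bonded_from_list <- function(u, tab, items) {
  b <- u[[tab]]
  for (it in items) {
    ends <- intersect(b$endpoints, names(it))
    for (e in ends) {
      pid <- as.integer(it[[e]])
      if (pid >= u$id_next) stop(sprintf("%s item references unknown particle id %d", tab, pid))
    }
    b$id <- c(b$id, as.integer(it$id))
    b$pot <- c(b$pot, list(pot_from_list(it$potential)))
    de <- it$dissociation_energy
    b$diss <- c(b$diss, if (is.null(de)) NA_real_ else as.numeric(de))
    b$energy <- c(b$energy, as.numeric(it$energy))
    for (e in b$endpoints) b[[e]] <- c(b[[e]], as.integer(it[[e]]))
  }
  u[[tab]] <- b
  invisible(u)
}

#' Save / load simulation state files
#' @param u a [universe]
#' @param path file path
#' @export
save_state <- function(u, path) {
  writeLines(to_json(u), path)
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  from_json(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

# ---- trajectory output -----------------------------------------------------

#' Append the current frame to trajectory files
#'
#' `write_xyz()` appends an XYZ frame (type name as the element column);
#' `write_traj_csv()` appends one row per live particle with id, type,
#' position, velocity, cluster and one column per declared species.
#'
#' @param u a [universe]
#' @param path output file
#' @param append append to an existing file (FALSE truncates)
#' @export
write_xyz <- function(u, path, append = TRUE) {
  s <- .live_slots(u)
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(c(as.character(length(s)),
               sprintf("step=%d time=%.10g", u$step_count, u$time)), con)
  if (length(s)) {
    writeLines(sprintf("%s %.10g %.10g %.10g", u$type_names[u$type_id[s]],
                       u$pos[s, 1], u$pos[s, 2], u$pos[s, 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
write_traj_csv <- function(u, path, append = TRUE) {
  s <- .live_slots(u)
  df <- data.frame(step = u$step_count, time = u$time, id = u$id[s],
                   type = u$type_names[u$type_id[s]],
                   x = u$pos[s, 1], y = u$pos[s, 2], z = u$pos[s, 3],
                   vx = u$vel[s, 1], vy = u$vel[s, 2], vz = u$vel[s, 3],
                   cluster = u$cluster_id[s])
  if (length(u$species)) {
    st <- as.data.frame(u$state[s, , drop = FALSE])
    names(st) <- u$species
    df <- cbind(df, st)
  }
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = !append || !file.exists(path),
                     append = append && file.exists(path), quote = FALSE)
  invisible(path)
}
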