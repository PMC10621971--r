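.onLoad <- function(libname, pkgname) {
  # model callbacks referenced by name from JSON state documents
  register_callback("crypt_step", .crypt_event)
  register_callback("dn_reaction", .dn_reaction)
  register_callback("dn_source", .dn_source_event)
  register_callback("signal_grid_source", .grid_source_event)
  invisible()
}
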