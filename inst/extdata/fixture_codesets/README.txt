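Synthetic fixture code sets
===========================

Every file in this directory is an INVENTED fixture code range used for
testing and for the synthetic record generator. These are NOT the real value
sets of WS 445.11-2014 or the GB/T clinical terminology standards; the real
code tables are licensed/governmental content and must be loaded by the user
at runtime (see load_codeset_dir()).

Format: two tab-separated columns, code <TAB> display term, UTF-8,
no header. File base name = codeset_id referenced by the default coding
rules.
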