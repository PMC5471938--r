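# Manually curated semantic-type exclusion list (template).
#
# The "manual" preset is a locally maintained expert list of ~70 semantic
# types judged unlikely to appear in informative relations. Its contents
# are institution-specific and are not shipped: add one ST code per line
# below (e.g. "geoa"). Lines starting with # are ignored. Using the preset
# while this file is empty is a configuration error.
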