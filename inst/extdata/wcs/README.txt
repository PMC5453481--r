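Optional external data (not distributed with the package)
==========================================================

Place here, if you have them:

  cnum-vhcm-lab-new.txt   the survey chip chart: one whitespace-delimited
                          row per chip with chip number, lightness-value
                          letter (A-J), hue column (0-40), Munsell codes,
                          and L* a* b* coordinates (read with
                          read_chip_coordinates(path, "wcs"))

  french_mode_map.csv     a chip_id,term table giving the French mode map
                          over the 330 chips (read with read_naming_table)

With these present, the acceptance tests additionally recompute the
published W values, rotation counts and index values on the real palette.
Nothing in the package requires them; all other analyses run on the
synthetic generators.
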