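# Variable dictionary, version 1.
# Category code lists for household WASH/housing variables and the asset set,
# with JMP-aligned improved/unimproved mappings and durable-material lists.
version: 1
assets:
  - radio
  - tv
  - fridge
  - phone
  - computer
  - motorcycle
  - bicycle
  - car
small_assets:          # asset-deprivation list: deprived iff owns <= 1 of these and no car
  - radio
  - tv
  - fridge
  - phone
  - computer
  - motorcycle
  - bicycle
water_sources:
  piped_dwelling: improved
  piped_yard: improved
  public_tap: improved
  tube_well: improved
  protected_well: improved
  protected_spring: improved
  rainwater: improved
  bottled_water: improved
  unprotected_well: unimproved
  unprotected_spring: unimproved
  tanker_truck: unimproved
  surface_water: unimproved
sanitation_types:
  flush_sewer: improved
  flush_septic: improved
  flush_pit: improved
  ventilated_pit: improved
  pit_with_slab: improved
  composting_toilet: improved
  flush_elsewhere: unimproved
  pit_no_slab: unimproved
  bucket: unimproved
  hanging_toilet: unimproved
  open_defecation: none
floor_materials:
  finished_cement: durable
  ceramic_tiles: durable
  parquet_wood: durable
  vinyl: durable
  earth_sand: not_durable
  dung: not_durable
  rudimentary_planks: not_durable
wall_materials:
  cement_blocks: durable
  bricks: durable
  stone_with_cement: durable
  cane_palm: not_durable
  mud: not_durable
  uncovered_adobe: not_durable
  reused_wood: not_durable
roof_materials:
  metal_sheet: durable
  finished_concrete: durable
  ceramic_tiles_roof: durable
  thatch_palm: not_durable
  sod: not_durable
  rustic_mat: not_durable
cooking_fuels:
  electricity_fuel: clean
  lpg: clean
  natural_gas: clean
  biogas: clean
  kerosene: dirty
  charcoal: dirty
  wood: dirty
  crop_residue: dirty
  dung_fuel: dirty
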