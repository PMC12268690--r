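data_theophylline_form_II
# Published unit-cell block for anhydrous theophylline Form II (100 K),
# orthorhombic Pna21; cell subset only, no atom sites.
_symmetry_space_group_name_H-M   'P n a 21'
_cell_length_a                   24.2655(8)
_cell_length_b                   3.76210(10)
_cell_length_c                   8.4743(2)
_cell_angle_alpha                90
_cell_angle_beta                 90
_cell_angle_gamma                90
_cell_formula_units_Z            4
_chemical_formula_sum            'C7 H8 N4 O2'
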