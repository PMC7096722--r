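data_restraint_dictionary
#
loop_
_chem_comp_atom.comp_id
_chem_comp_atom.atom_id
_chem_comp_atom.type_symbol
TOY C1  C 
TOY C2  C 
TOY C3  C 
TOY C4  C 
TOY C5  C 
TOY C6  C 
TOY C7  C 
TOY CL1 CL
TOY C8  C 
TOY C9  C 
#
loop_
_chem_comp_bond.comp_id
_chem_comp_bond.atom_id_1
_chem_comp_bond.atom_id_2
_chem_comp_bond.value_dist
_chem_comp_bond.value_dist_esd
TOY C1 C2  1.51 0.02
TOY C2 C3  1.39 0.02
TOY C3 C4  1.39 0.02
TOY C4 C5  1.39 0.02
TOY C5 C6  1.39 0.02
TOY C6 C7  1.39 0.02
TOY C7 C2  1.39 0.02
TOY C3 CL1 1.74 0.02
TOY C1 C8  1.53 0.02
TOY C8 C9  1.53 0.02
#
loop_
_chem_comp_angle.comp_id
_chem_comp_angle.atom_id_1
_chem_comp_angle.atom_id_2
_chem_comp_angle.atom_id_3
_chem_comp_angle.value_angle
_chem_comp_angle.value_angle_esd
TOY C2 C1 C8  112   2
TOY C1 C2 C3  120   2
TOY C1 C2 C7  120   2
TOY C3 C2 C7  120   2
TOY C2 C3 C4  120   2
TOY C2 C3 CL1 119.3 2
TOY C4 C3 CL1 120.7 2
TOY C3 C4 C5  120   2
TOY C4 C5 C6  120   2
TOY C5 C6 C7  120   2
TOY C2 C7 C6  120   2
TOY C1 C8 C9  112   2
#
loop_
_chem_comp_tor.comp_id
_chem_comp_tor.id
_chem_comp_tor.atom_id_1
_chem_comp_tor.atom_id_2
_chem_comp_tor.atom_id_3
_chem_comp_tor.atom_id_4
_chem_comp_tor.value_angle
_chem_comp_tor.value_angle_esd
_chem_comp_tor.period
TOY tor1 C9 C8 C1 C2 180 20 3
TOY tor2 C8 C1 C2 C3 90  20 2
#
loop_
_chem_comp_plane_atom.comp_id
_chem_comp_plane_atom.plane_id
_chem_comp_plane_atom.atom_id
_chem_comp_plane_atom.dist_esd
TOY plan1 C1  0.02
TOY plan1 C2  0.02
TOY plan1 C3  0.02
TOY plan1 C4  0.02
TOY plan1 C5  0.02
TOY plan1 C6  0.02
TOY plan1 C7  0.02
TOY plan1 CL1 0.02
#
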