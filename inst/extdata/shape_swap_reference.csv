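species,shape,structure,max_deformation_um,max_stress_kpa
pulex,uninduced,uninduced,95.2,22.1
pulex,induced,induced,34.4,11.3
pulex,uninduced,induced,16.9,11.0
pulex,induced,uninduced,187.0,28.0
longicephala,uninduced,uninduced,25.7,4.72
longicephala,induced,induced,7.14,7.45
longicephala,uninduced,induced,8.43,4.72
longicephala,induced,uninduced,21.7,7.45
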