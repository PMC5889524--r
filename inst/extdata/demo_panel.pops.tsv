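EAST_001	EAST
EAST_002	EAST
EAST_003	EAST
EAST_004	EAST
EAST_005	EAST
EAST_006	EAST
WEST_001	WEST
WEST_002	WEST
WEST_003	WEST
WEST_004	WEST
WEST_005	WEST
WEST_006	WEST
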