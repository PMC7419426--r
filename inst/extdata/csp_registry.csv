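csp_id,material,task,tool,label
CSP-01,asphalt,cutting,walk-behind saw,Cutting asphalt with walk-behind saw
CSP-02,asphalt,milling,milling machine,Milling asphalt with milling machine
CSP-03,concrete masonry unit,cutting,table saw,Cutting concrete masonry units with table saw
CSP-04,concrete masonry unit,cutting,powered portable saw,Cutting concrete masonry units with powered portable saw
CSP-05,concrete,cutting,saw,Cutting concrete with saw
CSP-06,concrete,coring,coring machine,Coring concrete with coring machine
CSP-07,concrete,drilling,electric hammer drill,Drilling concrete with electric hammer drill
CSP-08,concrete,grinding,"angle, surface, right angle, or flat grinder","Grinding concrete with angle, surface, right angle, or flat grinder"
CSP-09,concrete,grinding,counterbalanced ceiling grinder,Grinding concrete with counterbalanced ceiling grinder
CSP-10,concrete,scarifying or bush hammering,scarifier or bush hammer,Scarifying or bush hammering concrete
CSP-11,concrete,loading,concrete mixer truck,Loading concrete mixer truck
CSP-12,concrete,breaking,jackhammer,Breaking concrete with jackhammer
CSP-13,shot-crete,spraying,compressed air mixture,Spraying shot-crete with compressed air mixture
CSP-14,ceramic tiles,cutting,portable powered tile saw,Cutting ceramic tiles with portable powered tile saw
CSP-15,rock/sand/earth,mechanized moving,heavy equipment,Mechanized moving of rock/sand/earth with heavy equipment
CSP-16,rock/sand/earth,manual moving,hand tools,Manual moving of rock/sand/earth
CSP-17,rock/sand/earth,crushing and processing,stationary or mobile crusher,Crushing and processing rock/sand/earth with a stationary or mobile crusher
CSP-18,marble/granite,cutting,powered saw,Cutting marble and/or granite with a powered saw
CSP-19,cementicious material,mixing and pouring,hand tools,Mixing and pouring cementicious material
CSP-20,drywall,cutting,saw,Cutting drywall with a saw
CSP-21,drywall,grinding,sander or grinder,Grinding drywall with a sander or grinder
CSP-22,mortar,tuck point grinding,tuck point grinder,Tuck point grinding
CSP-23,fiber cement board,cutting,portable saw,Cutting fiber cement board with a portable saw
CSP-24,various,demolition,various,Demolition of rock or concrete structures
CSP-25,various,manual sweeping,broom,Manual sweeping of rock or concrete construction dust
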