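category_id	path	flags
araphid-pennate	cellular;eukaryota;stramenopiles;diatoms;araphid-pennate	diatom,stramenopile,eukaryote,lineage=diatoms
raphid-pennate	cellular;eukaryota;stramenopiles;diatoms;raphid-pennate	diatom,stramenopile,eukaryote,lineage=diatoms
polar-centric	cellular;eukaryota;stramenopiles;diatoms;polar-centric	diatom,stramenopile,eukaryote,lineage=diatoms
radial-centric	cellular;eukaryota;stramenopiles;diatoms;radial-centric	diatom,stramenopile,eukaryote,lineage=diatoms
pelagophytes	cellular;eukaryota;stramenopiles;pelagophytes	stramenopile,eukaryote,lineage=pelagophytes
eustigmatophytes	cellular;eukaryota;stramenopiles;eustigmatophytes	stramenopile,eukaryote,lineage=eustigmatophytes
haptophyte-prymnesiales	cellular;eukaryota;haptophytes;haptophyte-prymnesiales	eukaryote,lineage=haptophytes
haptophyte-coccolithales	cellular;eukaryota;haptophytes;haptophyte-coccolithales	eukaryote,lineage=haptophytes
chlorophytes	cellular;eukaryota;archaeplastida;chlorophytes	eukaryote,lineage=chlorophytes
alpha-rhodobacterales	cellular;bacteria;proteobacteria;alphaproteobacteria;alpha-rhodobacterales	prokaryote,alphaproteobacterium,lineage=alphaproteobacteria
alpha-rhizobiales	cellular;bacteria;proteobacteria;alphaproteobacteria;alpha-rhizobiales	prokaryote,alphaproteobacterium,lineage=alphaproteobacteria
gammaproteobacteria	cellular;bacteria;proteobacteria;gammaproteobacteria	prokaryote,lineage=gammaproteobacteria
chlorobi-a	cellular;bacteria;chlorobi;chlorobi-a	prokaryote,lineage=chlorobi
chlorobi-b	cellular;bacteria;chlorobi;chlorobi-b	prokaryote,lineage=chlorobi
verrucomicrobia-a	cellular;bacteria;verrucomicrobia;verrucomicrobia-a	prokaryote,lineage=verrucomicrobia
verrucomicrobia-b	cellular;bacteria;verrucomicrobia;verrucomicrobia-b	prokaryote,lineage=verrucomicrobia
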