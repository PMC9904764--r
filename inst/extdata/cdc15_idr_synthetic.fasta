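>cdc15_idr_synthetic 327-854 synthetic stand-in sequence
KGVSAELKATQESASKNAVLTKGLRTAQAAKQQAGLSFAASDAVLADADEQKKSTKNLTL
PQYDPVFLNDLQMGKLNQFNKDERGEQTSKRDTAPGGKKATDQARQAQHGASRNVDPGGF
QTGTNRRSVGPARANTGSSRLGVRARPLEQGGSASPRTQSVPSVQTAPPEGSKNQAARSN
HAQGSSSTGQKPAFNEGPTRSPFQTAFRRARTPQLAVDQNTPSRSDPDDSKKEPGGTMAP
ASSSSTKGSLQDHGTRADRADNEAPQEQAATPQANGTKSKDTGAVDRGGPIGRSDPRPAA
ANITGPRDLSQSIPAEEANNSDQLARATLGGSTLSNLLQQESGEREPKLEPQVASDMYKS
GQKNQATKANGHASTSVMKSAKNSSNLLLNASFKSGEGQTGDARRSSPDKGLNSNQSAQN
NGRNTSGSFEAVDVSITLSGGVKTNANSDGALDPIFRISSSTTSSAPTNYDAFSTGTRMQ
KEDSRFSGGSIEQASEDEGKRLTQSGANLSSDASGSASTNTSNQEGAS
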